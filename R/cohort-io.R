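# On-disk representation of a synthetic cohort: per-donor VCF 4.2 pairs,
# metadata TSV, truth TSVs. Writing is plain-text formatting; reading goes
# through vcfR.

vcf_header <- function(sample_id) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Reference trinucleotide context\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
}

write_donor_vcf <- function(calls, path, sample_id) {
  calls <- dplyr::arrange(calls, factor(.data$chrom, levels = CHROM_LEVELS),
                          .data$pos)
  info <- paste0(
    "CTX=", ifelse(is.na(calls$context), ".", calls$context),
    ";GENE=", ifelse(is.na(calls$gene), ".", calls$gene),
    ";CSQ=", ifelse(is.na(calls$consequence), ".", calls$consequence))
  body <- paste(
    calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
    ifelse(calls$caller_pass, "PASS", "lowconf"), info, "AD:DP",
    paste0(calls$depth - calls$alt_reads, ",", calls$alt_reads, ":",
           calls$depth),
    sep = "\t")
  writeLines(c(vcf_header(sample_id), body), path)
}

info_field <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
  m[m == "."] <- NA_character_
  m
}

read_donor_vcf <- function(path, sample_id) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    rlang::abort("reading cohort VCFs requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble::tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), alt_reads = integer(),
      depth = integer(), vaf = double(), caller_pass = logical(),
      context = character(), gene = character(), consequence = character()))
  }
  gt <- v@gt[, 2]
  ad <- vapply(strsplit(gt, ":"), `[`, character(1), 1)
  dp <- as.integer(vapply(strsplit(gt, ":"), `[`, character(1), 2))
  alt_reads <- as.integer(vapply(strsplit(ad, ","), `[`, character(1), 2))
  tibble::tibble(
    sample_id = sample_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    alt_reads = alt_reads,
    depth = dp,
    vaf = alt_reads / dp,
    caller_pass = fix$FILTER == "PASS",
    context = info_field(fix$INFO, "CTX"),
    gene = info_field(fix$INFO, "GENE"),
    consequence = info_field(fix$INFO, "CSQ")
  )
}

#' Write a synthetic cohort to disk
#'
#' Emits one blood and one tumor VCF 4.2 per donor (records sorted by
#' chromosome then position, read support as `AD`/`DP`), a donor metadata
#' TSV with one boolean column per treatment class, and two ground-truth
#' TSVs. [read_cohort()] round-trips the result exactly.
#'
#' @param cohort A `ch_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "ch_cohort"))
  if (nrow(cohort$donors) == 0) rlang::abort("cohort is empty")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    rlang::abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  readr::write_tsv(cohort$donors, file.path(out_dir, "donors.tsv"))
  readr::write_tsv(cohort$truth, file.path(out_dir, "truth_donors.tsv"))
  readr::write_tsv(cohort$truth_variants,
                   file.path(out_dir, "truth_variants.tsv"))
  for (id in cohort$donors$donor_id) {
    write_donor_vcf(cohort$calls[cohort$calls$sample_id == id, ],
                    file.path(out_dir, paste0(id, ".blood.vcf")), id)
    write_donor_vcf(cohort$tumor_calls[cohort$tumor_calls$sample_id == id, ],
                    file.path(out_dir, paste0(id, ".tumor.vcf")), id)
  }
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `ch_cohort` (without the generating `config`).
#' @export
read_cohort <- function(dir) {
  donors <- readr::read_tsv(file.path(dir, "donors.tsv"),
                            show_col_types = FALSE)
  truth <- readr::read_tsv(file.path(dir, "truth_donors.tsv"),
                           show_col_types = FALSE)
  truth_variants <- readr::read_tsv(file.path(dir, "truth_variants.tsv"),
                                    show_col_types = FALSE)
  calls <- purrr::map_dfr(donors$donor_id, function(id) {
    read_donor_vcf(file.path(dir, paste0(id, ".blood.vcf")), id)
  })
  tumor_calls <- purrr::map_dfr(donors$donor_id, function(id) {
    read_donor_vcf(file.path(dir, paste0(id, ".tumor.vcf")), id)
  })
  structure(list(
    donors = donors, calls = calls, tumor_calls = tumor_calls,
    truth = truth, truth_variants = truth_variants, config = NULL
  ), class = "ch_cohort")
}
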