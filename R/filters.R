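# The post-calling filter cascade that turns raw blood-vs-tumor ("reverse")
# variant calls into the full / mutect / mosaic somatic catalogs.
#
# All filters are tibble-in / tibble-out and strictly monotone: each step
# returns a subset of its input. Frequency comparisons are strict
# ("greater than"); ties are kept.

POPULATION_CUTOFFS <- c(PoN_TCGA = 0.002, PoN_HMF = 0.008, gnomAD = 3e-04)

#' Basic read-support filter
#'
#' Keeps variants that carry the caller's PASS flag, have at least two
#' supporting alternate reads, and a VAF strictly below 0.5 (a
#' heterozygous-germline guard: true clone mutations sit below 0.5 for
#' clone fractions under 1). Records with missing read support are
#' rejected and counted in a warning.
#'
#' @param calls Tibble with `caller_pass`, `alt_reads`, `vaf`.
#' @return Filtered tibble.
#' @export
basic_filters <- function(calls) {
  assert_calls(calls, c("caller_pass", "alt_reads", "vaf"))
  missing <- is.na(calls$alt_reads) | is.na(calls$vaf) |
    is.na(calls$caller_pass)
  if (any(missing)) {
    rlang::warn(sprintf("%d variant(s) with missing read support rejected",
                        sum(missing)))
  }
  keep <- !missing & calls$caller_pass & calls$alt_reads >= 2 &
    calls$vaf < 0.5
  calls[keep, , drop = FALSE]
}

merge_mask_intervals <- function(masks) {
  masks |>
    dplyr::mutate(start = as.numeric(.data$start),
                  end = as.numeric(.data$end)) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(grp = cumsum(.data$start >
                                 dplyr::lag(cummax(.data$end),
                                            default = -Inf))) |>
    dplyr::group_by(.data$chrom, .data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
}

#' Genomic mask filter
#'
#' Removes variants whose position falls inside any mask interval
#' (low-mappability, segmental duplication, simple repeat, masked region).
#' Mask intervals use the BED convention: 0-based, half-open; variant
#' positions are 1-based. Chromosomes absent from the mask are treated as
#' unmasked.
#'
#' @param calls Tibble with `chrom`, `pos`.
#' @param masks Tibble with `chrom`, `start`, `end` and optionally `track`.
#' @param tracks Optional character vector restricting which `track`
#'   values apply.
#' @return Filtered tibble.
#' @export
mask_filter <- function(calls, masks, tracks = NULL) {
  assert_calls(calls, c("chrom", "pos"))
  if (is.null(masks) || nrow(masks) == 0) return(calls)
  if (!is.null(tracks) && "track" %in% names(masks)) {
    masks <- masks[masks$track %in% tracks, , drop = FALSE]
  }
  if (nrow(masks) == 0) return(calls)
  hit <- positions_in_intervals(calls$chrom, calls$pos, masks)
  calls[!hit, , drop = FALSE]
}

# TRUE where the 1-based position falls in any 0-based half-open interval.
positions_in_intervals <- function(chrom, pos, intervals) {
  merged <- merge_mask_intervals(intervals[, c("chrom", "start", "end")])
  hit <- logical(length(pos))
  for (cm in unique(chrom)) {
    iv <- merged[merged$chrom == cm, , drop = FALSE]
    sel <- which(chrom == cm)
    if (nrow(iv) == 0) next
    p0 <- pos[sel] - 1L  # to 0-based
    idx <- findInterval(p0, iv$start)
    hit[sel] <- idx >= 1 & p0 < iv$end[pmax(idx, 1)]
  }
  hit
}

#' Read BED intervals into a mask tibble
#'
#' @param path BED file (chrom, start, end, optionally name).
#' @param track Label stored in the `track` column.
#' @return Tibble with `chrom`, `start`, `end`, `track`.
#' @export
read_bed_mask <- function(path, track = "masked") {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  tibble::tibble(chrom = bed[[1]], start = as.integer(bed[[2]]),
                 end = as.integer(bed[[3]]), track = track)
}

#' Merge adjacent SNVs into double-base substitutions
#'
#' Two single-nucleotide variants of the same sample at consecutive
#' positions on the same chromosome are merged into one double-base
#' substitution whose VAF is the mean of the pair. Runs of three or more
#' adjacent SNVs are paired left-greedily (a triplet yields one DBS plus
#' one SNV), which is deterministic on sorted input.
#'
#' @param calls Tibble of SNV calls.
#' @return Tibble in which merged pairs are replaced by DBS records.
#' @export
merge_dbs <- function(calls) {
  assert_calls(calls, c("sample_id", "chrom", "pos", "ref", "alt"))
  if (nrow(calls) == 0) return(calls)
  is_snv <- nchar(calls$ref) == 1 & nchar(calls$alt) == 1
  snvs <- calls[is_snv, , drop = FALSE]
  snvs <- snvs[order(snvs$sample_id, snvs$chrom, snvs$pos), , drop = FALSE]
  n <- nrow(snvs)
  if (n == 0) return(calls)
  new_run <- c(TRUE, snvs$sample_id[-1] != snvs$sample_id[-n] |
                 snvs$chrom[-1] != snvs$chrom[-n] |
                 snvs$pos[-1] != snvs$pos[-n] + 1)
  run <- cumsum(new_run)
  within <- seq_len(n) - match(run, run) + 1L
  # left-greedy pairing inside each run of adjacent positions
  pair_first <- within %% 2L == 1L &
    c(run[-1] == run[-n] & within[-1] == within[-n] + 1L, FALSE)
  pair_second <- c(FALSE, pair_first[-n])
  i1 <- which(pair_first)
  i2 <- i1 + 1L
  merged <- snvs[i1, , drop = FALSE]
  merged$ref <- paste0(snvs$ref[i1], snvs$ref[i2])
  merged$alt <- paste0(snvs$alt[i1], snvs$alt[i2])
  avg_int <- function(a, b) as.integer(round((a + b) / 2))
  if ("alt_reads" %in% names(snvs)) {
    merged$alt_reads <- avg_int(snvs$alt_reads[i1], snvs$alt_reads[i2])
  }
  if ("depth" %in% names(snvs)) {
    merged$depth <- avg_int(snvs$depth[i1], snvs$depth[i2])
  }
  if ("vaf" %in% names(snvs)) {
    merged$vaf <- (snvs$vaf[i1] + snvs$vaf[i2]) / 2
  }
  if ("caller_pass" %in% names(snvs)) {
    merged$caller_pass <- snvs$caller_pass[i1] & snvs$caller_pass[i2]
  }
  if ("context" %in% names(snvs)) merged$context <- NA_character_
  if ("gene" %in% names(snvs)) {
    merged$gene <- dplyr::coalesce(snvs$gene[i1], snvs$gene[i2])
  }
  out <- dplyr::bind_rows(merged,
                          snvs[!pair_first & !pair_second, , drop = FALSE],
                          calls[!is_snv, , drop = FALSE])
  out <- out[, names(calls)]
  out[order(out$sample_id, factor(out$chrom, levels = unique(calls$chrom)),
            out$pos), , drop = FALSE]
}

resolve_freq <- function(calls, resource_tbl) {
  key <- variant_key(calls)
  rkey <- variant_key(resource_tbl)
  resource_tbl$af[match(key, rkey)]
}

#' Panel-of-normals and population-frequency filter
#'
#' For each panel-of-normals resource, the removal threshold is the
#' maximum frequency of the supplied driver hotspot keys in that resource
#' (0 if absent): variants strictly more frequent than the hotspot are
#' removed, the rationale being that a true CH hotspot marks the highest
#' frequency a genuine somatic variant attains cohort-wide. Variants are
#' additionally removed when their frequency strictly exceeds the
#' resource-specific population cutoff (0.002 PoN_TCGA, 0.008 PoN_HMF,
#' 0.0003 gnomAD). Ties are kept.
#'
#' @param calls Call tibble.
#' @param resources Tibble with `chrom`, `pos`, `ref`, `alt`, `af`,
#'   `resource` (labels from `names(POPULATION_CUTOFFS)`).
#' @param hotspot_keys Character vector of `"chrom:pos:ref:alt"` keys (or a
#'   tibble with those columns) defining the hotspot threshold.
#' @param cutoffs Named numeric overriding the population cutoffs.
#' @return Filtered tibble.
#' @export
pon_filter <- function(calls, resources, hotspot_keys = character(),
                       cutoffs = POPULATION_CUTOFFS) {
  if (is.null(resources) || nrow(resources) == 0) return(calls)
  if (is.data.frame(hotspot_keys)) hotspot_keys <- variant_key(hotspot_keys)
  labels <- unique(resources$resource)
  unknown <- setdiff(labels, names(cutoffs))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown frequency resource label(s): ",
                        paste(unknown, collapse = ", ")))
  }
  remove <- logical(nrow(calls))
  for (lab in labels) {
    tbl <- resources[resources$resource == lab, , drop = FALSE]
    af <- resolve_freq(calls, tbl)
    af[is.na(af)] <- 0
    remove <- remove | af > cutoffs[[lab]]
    if (grepl("^PoN", lab) && length(hotspot_keys) > 0) {
      hs <- tbl$af[match(hotspot_keys, variant_key(tbl))]
      threshold <- max(c(hs, 0), na.rm = TRUE)
      remove <- remove | af > threshold
    }
  }
  calls[!remove, , drop = FALSE]
}

#' Common-SNP filter
#'
#' Removes variants whose allele-aware key (chrom, pos, ref, alt) appears
#' in any supplied common-polymorphism set (e.g. snp151Common, dbSNP).
#'
#' @param calls Call tibble.
#' @param snp_sets A tibble with `chrom`, `pos`, `ref`, `alt`, or a list of
#'   such tibbles.
#' @return Filtered tibble.
#' @export
common_snp_filter <- function(calls, snp_sets) {
  if (is.null(snp_sets)) return(calls)
  if (is.data.frame(snp_sets)) snp_sets <- list(snp_sets)
  keys <- unique(unlist(lapply(snp_sets, variant_key)))
  if (length(keys) == 0) return(calls)
  calls[!(variant_key(calls) %in% keys), , drop = FALSE]
}

#' Samples removed by the hypermutator rule
#'
#' @param counts Named numeric of per-sample mutation counts.
#' @param prob Percentile above which a sample is excluded.
#' @return Character vector of removed sample names (count strictly above
#'   the linear-interpolation percentile of the cohort burden).
#' @export
hypermutator_cut <- function(counts, prob = 0.975) {
  if (length(counts) < 2) {
    rlang::warn("fewer than 2 samples: hypermutator rule not applied")
    return(character())
  }
  names(counts)[counts > quantile(counts, prob, type = 7)]
}

#' Hypermutator sample filter
#'
#' Drops every variant of samples whose mutation count is strictly above
#' the 97.5th percentile of the per-sample burden across the cohort
#' (linear-interpolation percentile). Removed sample ids are attached as
#' the `removed_samples` attribute.
#'
#' @param calls Call tibble with `sample_id`.
#' @param prob Percentile (default 0.975).
#' @return Filtered tibble.
#' @export
hypermutator_filter <- function(calls, prob = 0.975) {
  assert_calls(calls, "sample_id")
  counts <- table(calls$sample_id)
  removed <- hypermutator_cut(setNames(as.numeric(counts), names(counts)),
                              prob)
  out <- calls[!(calls$sample_id %in% removed), , drop = FALSE]
  attr(out, "removed_samples") <- removed
  out
}

#' Intersect the full call set with a second caller's set
#'
#' Returns the subset of `full` whose (sample, chrom, pos, ref, alt) key is
#' also present in `other`, preserving `full`'s annotations; used to build
#' the mutect and mosaic catalogs from the full catalog.
#'
#' @param full Call tibble whose annotations are kept.
#' @param other Call tibble from the second caller / mosaic classifier.
#' @param label Catalog label stamped in the `set` column.
#' @return Subset tibble with a `set` column.
#' @export
intersect_callsets <- function(full, other, label = "intersection") {
  keep <- sample_variant_key(full) %in% sample_variant_key(other)
  out <- full[keep, , drop = FALSE]
  out$set <- label
  out
}

cascade_steps <- c("basic", "low_mappability", "dbs_merge", "pon_gnomad",
                   "common_snp", "region_masks", "hypermutator")

#' Run the full reverse-calling filter cascade
#'
#' Applies the post-calling filters in order: basic read-support filter,
#' low-mappability mask, DBS merging, panel-of-normals / population
#' frequency filter, common-SNP filter, segmental-duplication /
#' simple-repeat / masked-region filter, and the hypermutator sample rule.
#' The surviving variants form the full catalog; optional second-caller
#' and mosaic-classifier call sets cut the mutect and mosaic catalogs from
#' it by intersection.
#'
#' @param calls Raw reverse-calling variant tibble.
#' @param masks Mask tibble (`chrom`, `start`, `end`, `track`), tracks
#'   `low_mappability`, `segdup`, `simple_repeat`, `masked`.
#' @param resources Frequency resource tibble for [pon_filter()].
#' @param snp_sets Common SNP set(s) for [common_snp_filter()].
#' @param hotspot_keys Hotspot keys for the PoN threshold.
#' @param mutect_calls,mosaic_calls Optional call tibbles defining the
#'   mutect and mosaic catalogs.
#' @return Object of class `ch_cascade` with elements `full`, `mutect`,
#'   `mosaic` (or `NULL`) and `report`, a tibble of per-step
#'   (`step`, `variants_in`, `variants_out`).
#' @export
run_cascade <- function(calls, masks = NULL, resources = NULL,
                        snp_sets = NULL, hotspot_keys = character(),
                        mutect_calls = NULL, mosaic_calls = NULL) {
  steps <- list(
    basic = function(x) basic_filters(x),
    low_mappability = function(x) {
      mask_filter(x, masks, tracks = "low_mappability")
    },
    dbs_merge = function(x) merge_dbs(x),
    pon_gnomad = function(x) pon_filter(x, resources, hotspot_keys),
    common_snp = function(x) common_snp_filter(x, snp_sets),
    region_masks = function(x) {
      mask_filter(x, masks, tracks = c("segdup", "simple_repeat", "masked"))
    },
    hypermutator = function(x) hypermutator_filter(x)
  )
  report <- tibble::tibble(step = character(), variants_in = integer(),
                           variants_out = integer())
  cur <- calls
  for (nm in names(steps)) {
    n_in <- nrow(cur)
    cur <- tryCatch(steps[[nm]](cur), error = function(e) {
      rlang::abort(sprintf("cascade step '%s' failed: %s", nm,
                           conditionMessage(e)))
    })
    if (nrow(cur) > n_in) {
      rlang::abort(sprintf("cascade step '%s' is not monotone", nm))
    }
    report <- dplyr::bind_rows(report, tibble::tibble(
      step = nm, variants_in = n_in, variants_out = nrow(cur)))
  }
  structure(list(
    full = cur,
    mutect = if (!is.null(mutect_calls)) {
      intersect_callsets(cur, mutect_calls, "mutect")
    },
    mosaic = if (!is.null(mosaic_calls)) {
      intersect_callsets(cur, mosaic_calls, "mosaic")
    },
    report = report
  ), class = "ch_cascade")
}

#' @export
print.ch_cascade <- function(x, ...) {
  cat("<ch_cascade>\n")
  print(x$report, n = Inf)
  invisible(x)
}

#' Tidy a cascade report
#'
#' @param x A `ch_cascade`.
#' @param ... Unused.
#' @return The per-step report tibble with a `removed` column.
#' @exportS3Method generics::tidy
#' @export
tidy.ch_cascade <- function(x, ...) {
  dplyr::mutate(x$report, removed = .data$variants_in - .data$variants_out)
}
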