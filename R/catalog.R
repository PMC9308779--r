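# SBS96 mutation catalogs: building from calls and converting to matrices.

#' Build per-sample SBS96 mutation catalogs
#'
#' Counts the single-nucleotide variants of each sample into the 96
#' trinucleotide substitution channels. Purine-reference variants are
#' collapsed onto the pyrimidine-centric channels by reverse complement.
#' Non-SNV records (multi-base ref or alt) and variants whose context
#' cannot be resolved (e.g. contains `N`) are skipped and counted in the
#' `skipped` attribute.
#'
#' @param calls Tibble of variant calls with columns `sample_id`, `ref`,
#'   `alt` and either a `context` column (reference trinucleotide centered
#'   on the variant) or `chrom`/`pos` plus a `context_fun`.
#' @param context_fun Optional function `(chrom, pos) -> trinucleotide`
#'   used when `calls` carries no `context` column.
#' @return A wide tibble with `sample_id` and one integer column per SBS96
#'   channel, one row per sample; attribute `skipped` holds the number of
#'   records not catalogued.
#' @export
#' @examples
#' calls <- tibble::tibble(sample_id = "s1", ref = "C", alt = "T",
#'                         context = "ACG")
#' build_catalog(calls)
build_catalog <- function(calls, context_fun = NULL) {
  assert_calls(calls, c("sample_id", "ref", "alt"))
  channels <- sbs96_channels()
  if (!("context" %in% names(calls))) {
    if (is.null(context_fun)) {
      rlang::abort("calls carry no `context` column and no `context_fun` given")
    }
    assert_calls(calls, c("chrom", "pos"))
    calls$context <- context_fun(calls$chrom, calls$pos)
  }
  is_snv <- nchar(calls$ref) == 1 & nchar(calls$alt) == 1 &
    toupper(calls$ref) %in% DNA_BASES & toupper(calls$alt) %in% DNA_BASES
  snvs <- calls[is_snv, , drop = FALSE]
  snvs$channel <- sbs96_channel(snvs$context, snvs$ref, snvs$alt)
  usable <- !is.na(snvs$channel)
  skipped <- sum(!is_snv) + sum(!usable)
  snvs <- snvs[usable, , drop = FALSE]

  samples <- unique(calls$sample_id)
  if (length(samples) == 0) {
    out <- dplyr::bind_cols(
      tibble::tibble(sample_id = character()),
      tibble::as_tibble(matrix(integer(), 0, 96,
                               dimnames = list(NULL, channels)),
                        .name_repair = "minimal"))
    attr(out, "skipped") <- skipped
    return(out)
  }
  counts <- table(
    factor(snvs$sample_id, levels = samples),
    factor(snvs$channel, levels = channels)
  )
  counts <- matrix(as.integer(counts), nrow = length(samples),
                   dimnames = list(samples, channels))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = samples),
                          tibble::as_tibble(counts, .name_repair = "minimal"))
  attr(out, "skipped") <- skipped
  out
}

#' Convert a wide catalog tibble to a channels-by-samples matrix
#'
#' @param catalog Wide tibble from [build_catalog()] (`sample_id` + 96
#'   channel columns), or an existing 96-row matrix which is returned
#'   unchanged.
#' @return Numeric matrix, 96 rows (channels) by samples, with dimnames.
#' @export
catalog_matrix <- function(catalog) {
  channels <- sbs96_channels()
  if (is.matrix(catalog)) {
    if (nrow(catalog) != 96) rlang::abort("catalog matrix must have 96 rows")
    if (is.null(rownames(catalog))) rownames(catalog) <- channels
    if (is.null(colnames(catalog))) {
      colnames(catalog) <- paste0("sample", seq_len(ncol(catalog)))
    }
    return(catalog)
  }
  assert_calls(catalog, c("sample_id", channels[1]))
  m <- t(as.matrix(catalog[, channels]))
  colnames(m) <- catalog$sample_id
  rownames(m) <- channels
  storage.mode(m) <- "double"
  m
}

#' Average healthy-donor catalogs into a reference signature
#'
#' Normalizes each sample's 96-channel catalog to probabilities and averages
#' them channel-wise, the construction used to define a hematopoietic stem
#' cell signature from healthy blood genomes. Zero-total catalogs are
#' excluded with a warning.
#'
#' @param catalogs Wide catalog tibble (one row per healthy sample) or a
#'   96-row matrix.
#' @return Tibble with columns `channel` and `prob` summing to 1.
#' @export
compute_hsc_signature <- function(catalogs) {
  m <- catalog_matrix(catalogs)
  totals <- colSums(m)
  if (any(totals == 0)) {
    rlang::warn(sprintf("%d zero-total catalog(s) excluded", sum(totals == 0)))
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (ncol(m) == 0) rlang::abort("no catalog with positive total")
  probs <- sweep(m, 2, totals, "/")
  tibble::tibble(channel = rownames(m), prob = unname(rowMeans(probs)))
}

#' Coerce signature profiles to a 96 x k matrix
#'
#' Accepts a wide tibble (a `channel` column plus one column per
#' signature, e.g. [hsc_reference_profile()]), or an existing 96-row
#' matrix, and returns the channels-by-signatures matrix used by the
#' fitting functions.
#'
#' @param signatures Signature profiles in either representation.
#' @return Numeric matrix with 96 rows in SBS96 channel order.
#' @export
as_signature_matrix <- function(signatures) {
  if (is.matrix(signatures)) {
    if (nrow(signatures) != 96) rlang::abort("signature matrix must have 96 rows")
    return(signatures)
  }
  if (is.data.frame(signatures)) {
    if (!("channel" %in% names(signatures))) {
      rlang::abort("signature tibble must carry a `channel` column")
    }
    ord <- match(sbs96_channels(), signatures$channel)
    if (anyNA(ord)) rlang::abort("signature tibble must cover all 96 channels")
    cols <- setdiff(names(signatures), "channel")
    m <- as.matrix(signatures[ord, cols, drop = FALSE])
    rownames(m) <- sbs96_channels()
    return(m)
  }
  rlang::abort("unsupported signature representation")
}
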