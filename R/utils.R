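#' @importFrom rlang .data
#' @importFrom stats rbinom rpois runif rmultinom quantile median glm binomial
#'   coef cor.test p.adjust sd setNames
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

sample_variant_key <- function(x) {
  paste(x$sample_id, x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

assert_calls <- function(calls, cols = c("chrom", "pos", "ref", "alt")) {
  missing <- setdiff(cols, names(calls))
  if (length(missing) > 0) {
    rlang::abort(paste0("call table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  invisible(calls)
}

#' Cosine similarity between two non-negative profiles
#'
#' @param a,b Numeric vectors of equal length with non-negative entries
#'   (e.g. two 96-channel signature profiles).
#' @return A scalar in \[0, 1\]; 1 for proportional vectors.
#' @export
#' @examples
#' cosine_similarity(c(1, 0, 1), c(2, 0, 2))
cosine_similarity <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    rlang::abort("profiles must have equal length")
  }
  if (any(a < 0) || any(b < 0)) {
    rlang::abort("profiles must be non-negative")
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    rlang::abort("cosine similarity undefined for a zero vector")
  }
  sum(a * b) / (na * nb)
}
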