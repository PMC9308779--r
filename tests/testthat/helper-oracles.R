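# Independent brute-force oracles used to cross-check the package's
# vectorized / dynamic-programming implementations.

# O(n*m) per-variant interval scan (1-based positions vs 0-based
# half-open intervals).
naive_mask_hit <- function(calls, masks) {
  vapply(seq_len(nrow(calls)), function(i) {
    any(masks$chrom == calls$chrom[i] &
          masks$start <= calls$pos[i] - 1 &
          calls$pos[i] - 1 < masks$end)
  }, logical(1))
}

# Number of left-greedy adjacent SNV pairs, by direct run enumeration.
naive_adjacent_pairs <- function(calls) {
  total <- 0L
  for (s in unique(calls$sample_id)) {
    for (cm in unique(calls$chrom[calls$sample_id == s])) {
      pos <- sort(calls$pos[calls$sample_id == s & calls$chrom == cm])
      run_len <- 1L
      for (i in seq_along(pos)) {
        if (i > 1 && pos[i] == pos[i - 1] + 1) {
          run_len <- run_len + 1L
        } else {
          if (i > 1) total <- total + run_len %/% 2L
          run_len <- 1L
        }
      }
      total <- total + run_len %/% 2L
    }
  }
  total
}

# Independent SBS96 channel assignment via an explicit two-strand lookup
# table (one row per channel per strand representation).
naive_channel_table <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    rc1 <- function(b) chartr("ACGT", "TGCA", b)
    rcs <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                          "")[[1]]), collapse = "")
    rows <- list()
    for (ch in sbs96_channels()) {
      ctx <- paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7))
      ref <- substr(ch, 3, 3)
      alt <- substr(ch, 5, 5)
      rows[[length(rows) + 1]] <- data.frame(
        context = c(ctx, rcs(ctx)), ref = c(ref, rc1(ref)),
        alt = c(alt, rc1(alt)), channel = ch)
    }
    tbl <<- do.call(rbind, rows)
    tbl
  }
})

naive_channel <- function(context, ref, alt) {
  tbl <- naive_channel_table()
  key <- paste(context, ref, alt)
  tbl$channel[match(key, paste(tbl$context, tbl$ref, tbl$alt))]
}

# Exhaustive 4^k enumeration of the quantized-score distribution of a PWM
# under its background model.
enumerate_pwm_pvalues <- function(x, granularity = 1e-3) {
  scores <- clonehema:::pwm_log_odds(x, granularity)
  k <- nrow(scores)
  kmers <- do.call(expand.grid, rep(list(1:4), k))
  total <- apply(kmers, 1, function(idx) {
    sum(scores[cbind(seq_len(k), as.integer(idx))])
  })
  prob <- apply(kmers, 1, function(idx) {
    prod(x$background[as.integer(idx)])
  })
  agg <- tapply(prob, total, sum)
  score <- as.integer(names(agg))
  ord <- order(score)
  data.frame(score = score[ord], prob = as.numeric(agg)[ord])
}

# Pearson correlation and two-sided p-value from first principles.
manual_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Quick builder for call tibbles.
make_calls <- function(n, sample_id = "s1", chrom = "chr1",
                       pos = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- pos %||% sample.int(10000L, n)
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
    ref = sample(c("C", "T"), n, replace = TRUE),
    alt = sample(c("A", "G"), n, replace = TRUE),
    alt_reads = sample(2:20, n, replace = TRUE),
    depth = 50L, vaf = NA_real_, caller_pass = TRUE,
    context = NA_character_, gene = NA_character_,
    consequence = "noncoding"
  ) |>
    dplyr::mutate(vaf = alt_reads / depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
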