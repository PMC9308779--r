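# Variant-centric transcription-factor motif scanning: exact PWM
# score-to-p-value tables by dynamic programming, +/-15 bp window scans of
# the reference and alternate haplotypes, and the disruption/creation
# verdict at a binding-significance threshold.

#' Construct a position weight matrix object
#'
#' @param matrix Numeric matrix, motif positions x 4 (columns A, C, G, T),
#'   each row summing to 1.
#' @param tf_name Transcription factor name.
#' @param background Background base frequencies (A, C, G, T), summing
#'   to 1.
#' @param pseudocount Added to every matrix cell before log-odds scoring
#'   (the matrix is renormalized), guarding against zero probabilities.
#' @return Object of class `ch_pwm`.
#' @export
pwm <- function(matrix, tf_name = "TF", background = rep(0.25, 4),
                pseudocount = 0.001) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) rlang::abort("PWM must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 4) rlang::abort("PWM must have length >= 4")
  if (any(matrix < 0)) rlang::abort("PWM entries must be non-negative")
  if (any(abs(rowSums(matrix) - 1) > 1e-9)) {
    rlang::abort("PWM rows must sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-9) {
    rlang::abort("background must sum to 1")
  }
  if (any(background <= 0) && pseudocount <= 0) {
    rlang::abort("zero background frequency requires a pseudocount")
  }
  colnames(matrix) <- DNA_BASES
  structure(list(tf_name = tf_name, matrix = matrix,
                 background = setNames(background, DNA_BASES),
                 pseudocount = pseudocount),
            class = "ch_pwm")
}

#' @export
print.ch_pwm <- function(x, ...) {
  cat(sprintf("<ch_pwm> %s, length %d\n", x$tf_name, nrow(x$matrix)))
  invisible(x)
}

#' Read motifs from a MEME-format file
#'
#' Parses MEME minimal motif format (the `MOTIF` / `letter-probability
#' matrix` blocks) into a list of [pwm()] objects. Background frequencies
#' are taken from the `Background letter frequencies` line when present,
#' else uniform.
#'
#' @param path MEME file path.
#' @param pseudocount Passed to [pwm()].
#' @return Named list of `ch_pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 0.001) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) == 1 && bg_i < length(lines)) {
    tok <- strsplit(trimws(lines[bg_i + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    named <- setNames(vals[!is.na(vals)], tok[which(!is.na(vals)) - 1])
    if (all(DNA_BASES %in% names(named))) bg <- unname(named[DNA_BASES])
  }
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    j <- s + 1
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) {
      j <- j + 1
    }
    if (j > length(lines)) next
    rows <- list()
    j <- j + 1
    while (j <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[j])) {
      vals <- as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]])
      rows[[length(rows) + 1]] <- vals
      j <- j + 1
    }
    m <- do.call(rbind, rows)
    m <- m / rowSums(m)
    out[[name]] <- pwm(m, tf_name = name, background = bg,
                       pseudocount = pseudocount)
  }
  out
}

pwm_log_odds <- function(x, granularity = 1e-3) {
  m <- x$matrix + x$pseudocount
  m <- m / rowSums(m)
  llr <- log2(sweep(m, 2, x$background, "/"))
  matrix(as.integer(round(llr / granularity)), nrow(m), 4,
         dimnames = list(NULL, DNA_BASES))
}

#' Exact score-to-p-value table for a PWM
#'
#' Computes, by dynamic-programming convolution over motif positions, the
#' exact distribution of the quantized log-odds score of a random k-mer
#' under the background model, and from it the p-value
#' `P(score >= s)` for every attainable score. Scores are quantized to
#' integer multiples of `granularity` (log2-odds units); window scoring
#' uses the same per-position quantization, so table lookups are exact.
#'
#' @param x A `ch_pwm`.
#' @param granularity Score quantum in log2-odds units.
#' @return Object of class `ch_pwm_pvalues`: the quantized score matrix,
#'   a tibble (`score`, `prob`, `p_value`) over attainable quantized
#'   scores with `p_value` monotone non-increasing in `score`, and the
#'   granularity.
#' @export
score_pvalue_table <- function(x, granularity = 1e-3) {
  stopifnot(inherits(x, "ch_pwm"))
  scores <- pwm_log_odds(x, granularity)
  bg <- x$background
  # distribution of the running score sum, tracked with an offset
  cur <- c(1)
  cur_lo <- 0L
  for (i in seq_len(nrow(scores))) {
    s_i <- scores[i, ]
    new_lo <- cur_lo + min(s_i)
    new_hi <- (cur_lo + length(cur) - 1L) + max(s_i)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in seq_len(4)) {
      off <- (cur_lo + s_i[b]) - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new
    cur_lo <- new_lo
  }
  score <- seq.int(cur_lo, cur_lo + length(cur) - 1L)
  keep <- cur > 0
  tbl <- tibble::tibble(score = score, prob = cur)
  tbl$p_value <- rev(cumsum(rev(tbl$prob)))
  tbl <- tbl[keep, , drop = FALSE]
  structure(list(tf_name = x$tf_name, scores = scores,
                 table = tbl, granularity = granularity,
                 min_score = min(tbl$score), max_score = max(tbl$score)),
            class = "ch_pwm_pvalues")
}

#' Look up PWM match p-values for quantized scores
#'
#' @param tbl A `ch_pwm_pvalues` from [score_pvalue_table()].
#' @param score Integer quantized score(s) (sum of per-position quantized
#'   log-odds).
#' @return `P(background score >= score)`: 1 at or below the minimum
#'   attainable score, 0 above the maximum.
#' @export
pwm_pvalue <- function(tbl, score) {
  vapply(score, function(s) {
    if (s <= tbl$min_score) return(1)
    if (s > tbl$max_score) return(0)
    i <- findInterval(s - 1e-9, tbl$table$score) + 1
    # smallest attainable score >= s
    if (i > nrow(tbl$table)) 0 else tbl$table$p_value[i]
  }, numeric(1))
}

score_window <- function(scores_q, window) {
  k <- nrow(scores_q)
  chars <- strsplit(toupper(window), "")[[1]]
  n <- length(chars)
  if (n < k) return(integer(0))
  base_idx <- match(chars, DNA_BASES)
  vapply(seq_len(n - k + 1), function(off) {
    idx <- base_idx[off:(off + k - 1)]
    if (anyNA(idx)) return(NA_integer_)
    sum(scores_q[cbind(seq_len(k), idx)])
  }, integer(1))
}

#' Scan the reference and alternate haplotype windows of a variant
#'
#' Scores every offset of the motif on both strands of each haplotype
#' window (the variant +/-15 bp on the reference sequence, and the same
#' window with the alternate base substituted) and returns the minimum
#' match p-value per haplotype.
#'
#' @param x A `ch_pwm` or a precomputed `ch_pwm_pvalues`.
#' @param ref_window,alt_window Haplotype sequences (characters over
#'   ACGT).
#' @param granularity Used when `x` is a `ch_pwm`.
#' @return Named numeric `c(p_ref, p_alt)`; `NA` if the windows are
#'   shorter than the motif.
#' @export
scan_variant <- function(x, ref_window, alt_window, granularity = 1e-3) {
  tbl <- if (inherits(x, "ch_pwm_pvalues")) x else {
    score_pvalue_table(x, granularity)
  }
  best_p <- function(window) {
    s <- c(score_window(tbl$scores, window),
           score_window(tbl$scores, revcomp(window)))
    s <- s[!is.na(s)]
    if (length(s) == 0) return(NA_real_)
    min(pwm_pvalue(tbl, max(s)))
  }
  c(p_ref = best_p(ref_window), p_alt = best_p(alt_window))
}

#' Disruption/creation verdict for a binding-site scan
#'
#' A variant disrupts a binding site when the best match is significant
#' (p < alpha) on the reference haplotype but not on the alternate, and
#' creates one in the opposite case; any other combination (both or
#' neither significant) is `none`.
#'
#' @param p_ref,p_alt Minimum match p-values of the two haplotypes.
#' @param alpha Binding significance threshold (default 1e-4).
#' @return Character vector over `disruption`, `creation`, `none`.
#' @export
classify_binding_change <- function(p_ref, p_alt, alpha = 1e-4) {
  dplyr::case_when(
    p_ref < alpha & p_alt >= alpha ~ "disruption",
    p_alt < alpha & p_ref >= alpha ~ "creation",
    TRUE ~ "none"
  )
}

#' Restrict mutations to the regulatory scanning context
#'
#' Builds the motif-scanning worklist: mutations falling inside both an
#' H3K27ac peak and an enhancer element, where the enhancer's annotated
#' target gene belongs to the CH driver compendium. Enhancers without a
#' target annotation are skipped and counted.
#'
#' @param calls Call tibble with `chrom`, `pos`.
#' @param h3k27ac Interval tibble (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @param enhancers Interval tibble with an additional `target_gene`
#'   column.
#' @param compendium_genes Character vector of CH driver genes.
#' @return The subset of `calls` with a `target_gene` column; attribute
#'   `unannotated_enhancers` counts enhancers lacking a target.
#' @export
filter_regulatory_context <- function(calls, h3k27ac, enhancers,
                                      compendium_genes) {
  assert_calls(calls, c("chrom", "pos"))
  assert_calls(enhancers, c("chrom", "start", "end", "target_gene"))
  unannot <- sum(is.na(enhancers$target_gene))
  enhancers <- enhancers[!is.na(enhancers$target_gene), , drop = FALSE]
  in_peak <- if (is.null(h3k27ac) || nrow(h3k27ac) == 0) {
    rep(FALSE, nrow(calls))
  } else {
    positions_in_intervals(calls$chrom, calls$pos, h3k27ac)
  }
  enh <- enhancers[enhancers$target_gene %in% compendium_genes, ,
                   drop = FALSE]
  out <- calls[in_peak, , drop = FALSE]
  out$target_gene <- NA_character_
  if (nrow(out) > 0 && nrow(enh) > 0) {
    for (i in seq_len(nrow(out))) {
      hit <- enh$chrom == out$chrom[i] &
        enh$start <= out$pos[i] - 1 & out$pos[i] - 1 < enh$end
      if (any(hit)) out$target_gene[i] <- enh$target_gene[which(hit)[1]]
    }
  }
  res <- out[!is.na(out$target_gene), , drop = FALSE]
  attr(res, "unannotated_enhancers") <- unannot
  res
}

#' Scan a regulatory worklist against a motif set
#'
#' For each worklist mutation and each expressed transcription factor
#' motif, extracts the variant +/-15 bp windows from the genome, scores
#' both haplotypes, and reports the binding verdict.
#'
#' @param worklist Output of [filter_regulatory_context()] with `ref`,
#'   `alt` columns.
#' @param pwms Named list of `ch_pwm` (e.g. [read_meme()]), already
#'   restricted to TFs expressed in the reference cell population.
#' @param genome Named character vector or list of chromosome sequences.
#' @param flank Window half-width in bp (default 15).
#' @param alpha Binding significance threshold.
#' @param granularity Score quantum for the p-value tables.
#' @return Tibble of binding events: variant key columns, `tf_name`,
#'   `p_ref`, `p_alt`, `verdict`, `target_gene`.
#' @export
scan_binding_events <- function(worklist, pwms, genome, flank = 15,
                                alpha = 1e-4, granularity = 1e-3) {
  if (nrow(worklist) == 0 || length(pwms) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          tf_name = character(), p_ref = double(),
                          p_alt = double(), verdict = character(),
                          target_gene = character()))
  }
  tables <- lapply(pwms, score_pvalue_table, granularity = granularity)
  purrr::map_dfr(seq_len(nrow(worklist)), function(i) {
    v <- worklist[i, ]
    seqs <- as.character(genome[[v$chrom]])
    lo <- max(1, v$pos - flank)
    hi <- min(nchar(seqs), v$pos + flank)
    ref_window <- substr(seqs, lo, hi)
    offset <- v$pos - lo + 1
    alt_window <- ref_window
    substr(alt_window, offset, offset) <- v$alt
    purrr::map_dfr(tables, function(tbl) {
      p <- scan_variant(tbl, ref_window, alt_window)
      tibble::tibble(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        tf_name = tbl$tf_name, p_ref = p[["p_ref"]], p_alt = p[["p_alt"]],
        verdict = classify_binding_change(p[["p_ref"]], p[["p_alt"]],
                                          alpha),
        target_gene = v$target_gene %||% NA_character_
      )
    })
  })
}
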