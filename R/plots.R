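# ggplot2 views of the main result types.

#' Plot a 96-channel signature profile
#'
#' Standard SBS96 barplot: channels in pyrimidine-centric order, faceted
#' by substitution class.
#'
#' @param signatures A signature tibble (`channel` + probability columns),
#'   a `ch_signatures` object, or a 96 x k matrix.
#' @return A ggplot.
#' @export
plot_signature <- function(signatures) {
  if (inherits(signatures, "ch_signatures")) {
    signatures <- signatures$signatures
  }
  m <- as_signature_matrix(signatures)
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  names(df) <- colnames(m) %||% paste0("S", seq_len(ncol(m)))
  df$channel <- factor(rownames(m), levels = sbs96_channels())
  df <- tidyr::pivot_longer(df, -"channel", names_to = "signature",
                            values_to = "prob")
  df$class <- paste0(substr(df$channel, 3, 3), ">", substr(df$channel, 5, 5))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$prob,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(signature ~ class, scales = "free_x") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "probability")
}

#' @rdname plot_signature
#' @param object A `ch_signatures` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ch_signatures <- function(object, ...) plot_signature(object)

#' Plot the binned age versus HSC-exposure trend
#'
#' @param object A `ch_trend` from [age_exposure_trend()].
#' @param ... Unused.
#' @return A ggplot with per-bin mean exposure and a +/- 1 sd ribbon.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ch_trend <- function(object, ...) {
  b <- object$bins[!is.na(object$bins$age_bin), ]
  ggplot2::ggplot(b, ggplot2::aes(x = .data$mid, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      fill = "lightblue", alpha = 0.6) +
    ggplot2::geom_line(color = "darkblue") +
    ggplot2::geom_point(color = "darkblue") +
    ggplot2::labs(
      x = "age (years)", y = "HSC-signature mutations",
      subtitle = sprintf("Pearson r = %.2f, p = %.2g", object$r,
                         object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a filter-cascade report
#'
#' @param object A `ch_cascade` from [run_cascade()].
#' @param ... Unused.
#' @return A ggplot of variants surviving each cascade step.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ch_cascade <- function(object, ...) {
  r <- object$report
  r$step <- factor(r$step, levels = r$step)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$step,
                                  y = .data$variants_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = .data$variants_in - .data$variants_out), vjust = -0.3,
      size = 3) +
    ggplot2::labs(x = NULL, y = "variants remaining",
                  subtitle = "labels: variants removed at each step") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Heatmap of gene co-occurrence
#'
#' @param cooc Tibble from [cooccurrence()].
#' @param value `"jaccard"` or `"comut_freq"`.
#' @return A ggplot tile map over gene pairs.
#' @export
plot_cooccurrence <- function(cooc, value = c("jaccard", "comut_freq")) {
  value <- match.arg(value)
  both <- dplyr::bind_rows(
    cooc,
    dplyr::rename(cooc, gene_a = "gene_b", gene_b = "gene_a"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$gene_a, y = .data$gene_b,
                                     fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
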