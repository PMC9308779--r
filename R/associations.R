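# Logistic-regression associations of CH status with age, sex and
# treatment exposure; gene-level treatment associations with BH
# correction; the age-exposure trend.

logit_tidy <- function(fit) {
  broom::tidy(fit) |>
    dplyr::mutate(
      conf.low = .data$estimate - 1.96 * .data$std.error,
      conf.high = .data$estimate + 1.96 * .data$std.error
    ) |>
    dplyr::select("term", coefficient = "estimate", "conf.low",
                  "conf.high", "p.value")
}

detect_separation <- function(fit) {
  probs <- fit$fitted.values
  !fit$converged || any(probs > 1 - 1e-8) || any(probs < 1e-8)
}

#' Multivariable logistic model of CH status
#'
#' Fits a maximum-likelihood logistic regression of CH case status on age
#' (years, untransformed), sex, and cytotoxic / non-cytotoxic treatment
#' indicators, reporting Wald 95% confidence intervals and p-values per
#' term. Degenerate outcomes (all donors CH, or perfect separation) are
#' flagged and the coefficient table withheld.
#'
#' @param donors Donor tibble with `donor_id`, `age`, `sex`, `cytotoxic`,
#'   `non_cytotoxic`.
#' @param ch_calls Tibble with `donor_id`, `is_CH`
#'   (e.g. [classify_cohort()] output).
#' @return Tibble with `term`, `coefficient` (log-odds), `conf.low`,
#'   `conf.high`, `p.value`; attribute `separation` flags a degenerate
#'   fit (in which case the tibble has zero rows).
#' @export
fit_ch_model <- function(donors, ch_calls) {
  assert_calls(donors, c("donor_id", "age", "sex", "cytotoxic",
                         "non_cytotoxic"))
  d <- dplyr::inner_join(donors, ch_calls[, c("donor_id", "is_CH")],
                         by = "donor_id")
  if (length(unique(d$is_CH)) < 2) {
    rlang::warn("degenerate outcome: all donors share one CH status")
    out <- logit_tidy(glm(is_CH ~ 1, data = d, family = binomial()))[0, ]
    attr(out, "separation") <- TRUE
    return(out)
  }
  fit <- glm(is_CH ~ age + sex + cytotoxic + non_cytotoxic,
             data = d, family = binomial())
  if (detect_separation(fit)) {
    rlang::warn("perfect separation detected: coefficients withheld")
    out <- logit_tidy(fit)[0, ]
    attr(out, "separation") <- TRUE
    return(out)
  }
  out <- logit_tidy(fit)
  attr(out, "separation") <- FALSE
  out
}

#' Gene-level treatment associations with BH correction
#'
#' For each gene and each treatment family, fits a logistic regression of
#' the gene's mutated status on the treatment indicator adjusted for age
#' and sex, and corrects p-values of the treatment term across genes
#' within each treatment family by Benjamini-Hochberg FDR. Genes mutated
#' in fewer than `min_mutated` donors are skipped and reported.
#'
#' @param mat Logical donors x genes matrix (see [donor_gene_matrix()]).
#' @param donors Donor tibble with `donor_id`, `age`, `sex` and one
#'   logical column per treatment.
#' @param treatments Character vector of treatment column names.
#' @param min_mutated Minimum mutated donors for a gene to be tested.
#' @return Tibble with `gene`, `treatment`, `coefficient`, `conf.low`,
#'   `conf.high`, `p.value`, `q.value`; skipped genes in attribute
#'   `skipped`.
#' @export
gene_treatment_associations <- function(mat, donors, treatments,
                                        min_mutated = 5) {
  assert_calls(donors, c("donor_id", "age", "sex", treatments))
  for (tr in treatments) {
    if (length(unique(donors[[tr]])) < 2) {
      rlang::abort(sprintf("treatment '%s' is constant across donors", tr))
    }
  }
  mat <- as.matrix(mat) > 0
  counts <- colSums(mat)
  skipped <- colnames(mat)[counts < min_mutated]
  genes <- colnames(mat)[counts >= min_mutated]
  res <- purrr::map_dfr(treatments, function(tr) {
    fam <- purrr::map_dfr(genes, function(g) {
      d <- donors
      d$mutated <- mat[match(d$donor_id, rownames(mat)), g]
      fit <- glm(stats::as.formula(paste("mutated ~", tr, "+ age + sex")),
                 data = d, family = binomial())
      row <- logit_tidy(fit)[2, ]
      tibble::tibble(gene = g, treatment = tr,
                     coefficient = row$coefficient,
                     conf.low = row$conf.low, conf.high = row$conf.high,
                     p.value = row$p.value)
    })
    fam$q.value <- p.adjust(fam$p.value, method = "BH")
    fam
  })
  attr(res, "skipped") <- skipped
  res
}

#' Age versus HSC-signature exposure trend
#'
#' Bins donors by age, summarizes the mean and standard deviation of their
#' HSC-signature exposure per bin, and reports the Pearson correlation of
#' exposure with age on the unbinned data — the age signal expected of
#' mutations accumulated by hematopoietic stem cell divisions.
#'
#' @param exposures Numeric vector of per-donor HSC exposures.
#' @param ages Numeric vector of donor ages (years, positive).
#' @param bin_width Age bin width in years.
#' @return Object of class `ch_trend`: list with `bins` (tibble
#'   `age_bin`, `mid`, `n`, `mean`, `sd`), `r`, `p_value`, `n`.
#' @export
age_exposure_trend <- function(exposures, ages, bin_width = 5) {
  stopifnot(length(exposures) == length(ages))
  if (any(ages <= 0)) rlang::abort("ages must be positive")
  breaks <- seq(floor(min(ages) / bin_width) * bin_width,
                ceiling(max(ages) / bin_width) * bin_width + bin_width,
                by = bin_width)
  bin <- cut(ages, breaks, right = FALSE)
  if (length(unique(bin[!is.na(bin)])) < 2) {
    rlang::warn("all ages fall in one bin")
  }
  bins <- tibble::tibble(exposure = exposures, age_bin = bin) |>
    dplyr::group_by(.data$age_bin) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$exposure),
                     sd = sd(.data$exposure), .groups = "drop") |>
    dplyr::mutate(mid = breaks[as.integer(.data$age_bin)] + bin_width / 2)
  ct <- cor.test(ages, exposures, method = "pearson")
  structure(list(bins = bins, r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(ages)),
            class = "ch_trend")
}

#' @export
print.ch_trend <- function(x, ...) {
  cat(sprintf("<ch_trend> Pearson r = %.3f (p = %.3g, n = %d)\n",
              x$r, x$p_value, x$n))
  invisible(x)
}

#' Tidy the binned age-exposure trend
#'
#' @param x A `ch_trend`.
#' @param ... Unused.
#' @return The per-bin summary tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.ch_trend <- function(x, ...) x$bins

#' One-row summary of an age-exposure trend
#'
#' @param x A `ch_trend`.
#' @param ... Unused.
#' @return One-row tibble with `r`, `p_value`, `n`.
#' @exportS3Method generics::glance
#' @export
glance.ch_trend <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, n = x$n)
}
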