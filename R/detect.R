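# Classification of donors as clonal-hematopoiesis cases: driver-gene
# mutation tiers plus the hematopoiesis-mutations-per-year median rule.

NONSILENT <- c("missense", "nonsense", "frameshift", "splice",
               "inframe_indel")

COMPENDIUM_TIERS <- c("known_CH", "myeloid_driver",
                      "discovered_primary_metastasis", "discovered_targeted")

# Basis labels in cumulative tier order (highest priority first).
CH_BASIS_LEVELS <- c("known_gene_germline_calling",
                     "known_gene_reverse_calling",
                     "discovered_gene", "targeted_gene",
                     "rate_threshold", "none")

#' Discovery input VAF filter
#'
#' Removes blood somatic mutations with VAF above 0.4 before driver
#' discovery, excluding residual germline leakage and large-clone
#' ambiguity; a VAF of exactly 0.4 is kept.
#'
#' @param calls Call tibble with a `vaf` column.
#' @param max_vaf Cutoff (default 0.4).
#' @return Filtered tibble.
#' @export
discovery_input_filter <- function(calls, max_vaf = 0.4) {
  assert_calls(calls, "vaf")
  calls[calls$vaf <= max_vaf, , drop = FALSE]
}

#' Is a gene expressed in the reference cell population?
#'
#' A gene counts as expressed when the maximum of its per-cell expression
#' distribution is strictly above the cutoff (default 15 fpkm), the
#' vetting used against CD34+ hematopoietic cells.
#'
#' @param values Numeric vector of per-cell expression values (fpkm).
#' @param cutoff Expression cutoff in fpkm.
#' @return Logical scalar.
#' @export
expression_vetting <- function(values, cutoff = 15) {
  if (length(values) == 0) rlang::abort("no expression values supplied")
  max(values) > cutoff
}

#' Rate of hematopoiesis mutations per year of age
#'
#' @param hsc_exposure Mutation count attributed to the HSC signature.
#' @param age Donor age in years (> 0).
#' @return `hsc_exposure / age` (vectorized).
#' @export
hsc_rate_per_year <- function(hsc_exposure, age) {
  if (any(age <= 0)) rlang::abort("age must be positive")
  hsc_exposure / age
}

tier_to_basis <- function(tier, in_germline_calling) {
  dplyr::case_when(
    tier == "known_CH" & in_germline_calling ~ "known_gene_germline_calling",
    tier == "known_CH" ~ "known_gene_reverse_calling",
    tier %in% c("myeloid_driver", "discovered_primary_metastasis") ~
      "discovered_gene",
    tier == "discovered_targeted" ~ "targeted_gene",
    TRUE ~ "none"
  )
}

#' Classify a cohort into CH cases
#'
#' Donors carrying a nonsilent mutation in a compendium gene are CH cases,
#' with the highest-priority applicable basis in the cumulative tier order
#' (known gene seen by germline calling, known gene by reverse calling,
#' discovered gene, targeted-cohort gene). The median rate of
#' hematopoiesis mutations per year of age is then computed across these
#' driver-mutated donors, and every remaining donor whose rate is strictly
#' greater than that median is also called a CH case (basis
#' `rate_threshold`).
#'
#' @param donors Donor tibble with `donor_id`, `age`.
#' @param calls Call tibble with `sample_id`, `gene`, `consequence`, and
#'   optionally `in_germline_calling` (logical; defaults to `FALSE`,
#'   i.e. reverse-calling provenance).
#' @param compendium Tibble with `gene` and `tier` (one of `known_CH`,
#'   `myeloid_driver`, `discovered_primary_metastasis`,
#'   `discovered_targeted`).
#' @param exposures Tibble with `sample_id` and `hsc_exposure` (mutation
#'   counts attributed to the HSC signature), e.g. a renamed column of
#'   [fit_exposures()] output.
#' @return Tibble with one row per donor: `donor_id`, `is_CH`, `basis`,
#'   `n_driver_mutations`, `hsc_rate_per_year`; the median rate used by
#'   the rate rule is attached as attribute `median_rate`.
#' @export
classify_cohort <- function(donors, calls, compendium, exposures) {
  assert_calls(donors, c("donor_id", "age"))
  assert_calls(compendium, c("gene", "tier"))
  bad <- setdiff(compendium$tier, COMPENDIUM_TIERS)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown compendium tier(s): ",
                        paste(bad, collapse = ", ")))
  }
  if (!("in_germline_calling" %in% names(calls))) {
    calls$in_germline_calling <- FALSE
  }
  driver_calls <- calls |>
    dplyr::filter(.data$consequence %in% NONSILENT,
                  .data$gene %in% compendium$gene) |>
    dplyr::left_join(compendium, by = "gene") |>
    dplyr::mutate(basis = tier_to_basis(.data$tier,
                                        .data$in_germline_calling))
  per_donor <- driver_calls |>
    dplyr::group_by(donor_id = .data$sample_id) |>
    dplyr::summarise(
      basis = CH_BASIS_LEVELS[min(c(match(.data$basis, CH_BASIS_LEVELS),
                                    length(CH_BASIS_LEVELS)))],
      n_driver_mutations = dplyr::n(), .groups = "drop")

  out <- donors |>
    dplyr::select("donor_id", "age") |>
    dplyr::left_join(per_donor, by = "donor_id") |>
    dplyr::left_join(
      dplyr::select(exposures, "sample_id", "hsc_exposure"),
      by = c(donor_id = "sample_id")) |>
    dplyr::mutate(
      n_driver_mutations = dplyr::coalesce(.data$n_driver_mutations, 0L),
      hsc_exposure = dplyr::coalesce(.data$hsc_exposure, 0),
      hsc_rate_per_year = hsc_rate_per_year(.data$hsc_exposure, .data$age)
    )

  mutated <- !is.na(out$basis)
  if (!any(mutated)) {
    rlang::warn("no driver-mutated donor: rate-threshold rule skipped")
    med <- NA_real_
  } else {
    med <- median(out$hsc_rate_per_year[mutated])
    out$basis[!mutated & out$hsc_rate_per_year > med] <- "rate_threshold"
  }
  out$basis[is.na(out$basis)] <- "none"
  out$is_CH <- out$basis != "none"
  out <- out[, c("donor_id", "is_CH", "basis", "n_driver_mutations",
                 "hsc_rate_per_year")]
  attr(out, "median_rate") <- med
  out
}

#' Cumulative CH case counts by detection tier
#'
#' @param ch_calls Output of [classify_cohort()].
#' @return Tibble with `basis`, `n` (donors whose best basis is that tier)
#'   and `cumulative` counts in the tier order of the detection criteria.
#' @export
ch_tier_counts <- function(ch_calls) {
  tiers <- setdiff(CH_BASIS_LEVELS, "none")
  n <- vapply(tiers, function(b) sum(ch_calls$basis == b), integer(1))
  tibble::tibble(basis = tiers, n = n, cumulative = cumsum(n))
}

#' Donor-by-gene mutation matrix from calls
#'
#' @param calls Call tibble with `sample_id`, `gene`, `consequence`.
#' @param genes Genes to include as columns (default: all mutated genes).
#' @param nonsilent_only Restrict to nonsilent consequences.
#' @return Logical matrix, donors x genes.
#' @export
donor_gene_matrix <- function(calls, genes = NULL, nonsilent_only = TRUE) {
  assert_calls(calls, c("sample_id", "gene"))
  x <- calls[!is.na(calls$gene), , drop = FALSE]
  genes <- genes %||% sort(unique(x$gene))
  if (nonsilent_only && "consequence" %in% names(x)) {
    x <- x[x$consequence %in% NONSILENT, , drop = FALSE]
  }
  donors <- sort(unique(calls$sample_id))
  m <- matrix(FALSE, length(donors), length(genes),
              dimnames = list(donors, genes))
  x <- x[x$gene %in% genes, , drop = FALSE]
  m[cbind(match(x$sample_id, donors), match(x$gene, genes))] <- TRUE
  m
}

#' Pairwise co-occurrence of mutated genes
#'
#' Computes, for every gene pair, the Jaccard index of the donor sets
#' mutated in each gene and the cohort frequency of co-mutation. Pairs in
#' which a gene has no mutated donor get `NA` Jaccard.
#'
#' @param mat Logical/binary donors x genes matrix
#'   (see [donor_gene_matrix()]).
#' @return Tibble with `gene_a`, `gene_b`, `jaccard`, `comut_freq`
#'   (symmetric; each unordered pair reported once, `gene_a < gene_b`).
#' @export
cooccurrence <- function(mat) {
  mat <- as.matrix(mat) > 0
  genes <- colnames(mat)
  pairs <- utils::combn(seq_along(genes), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- mat[, pairs[1, i]]
    b <- mat[, pairs[2, i]]
    inter <- sum(a & b)
    uni <- sum(a | b)
    tibble::tibble(
      gene_a = genes[pairs[1, i]], gene_b = genes[pairs[2, i]],
      # undefined when either gene has no mutated donor
      jaccard = if (sum(a) == 0 || sum(b) == 0) NA_real_ else inter / uni,
      comut_freq = inter / nrow(mat)
    )
  })
}

#' Distribution of donors by number of mutated compendium genes
#'
#' @param mat Logical/binary donors x genes matrix.
#' @return Tibble with `n_genes` (>= 1), `n_donors`, `fraction` (over
#'   donors with at least one mutated gene; fractions sum to 1).
#' @export
mutation_multiplicity <- function(mat) {
  mat <- as.matrix(mat) > 0
  k <- rowSums(mat)
  k <- k[k >= 1]
  if (length(k) == 0) {
    return(tibble::tibble(n_genes = integer(), n_donors = integer(),
                          fraction = double()))
  }
  tab <- table(k)
  tibble::tibble(
    n_genes = as.integer(names(tab)),
    n_donors = as.integer(tab),
    fraction = as.integer(tab) / length(k)
  )
}
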