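demo_compendium <- function() {
  tibble::tibble(
    gene = c("DNMT3A", "JAK2", "TET2", "ASXL1", "PPM1D", "CHEK2"),
    tier = c("known_CH", "known_CH", "known_CH", "myeloid_driver",
             "discovered_primary_metastasis", "discovered_targeted")
  )
}

test_that("the discovery VAF filter removes only variants above 0.4", {
  calls <- make_calls(3, pos = c(1L, 2L, 3L) * 10L)
  calls$vaf <- c(0.41, 0.40, 0.10)
  out <- discovery_input_filter(calls)
  expect_equal(out$vaf, c(0.40, 0.10))  # 0.4 exactly is kept
  # brute-force threshold scan on a mixed set
  set.seed(9)
  calls2 <- make_calls(200)
  calls2$vaf <- runif(200, 0, 0.6)
  expect_equal(discovery_input_filter(calls2),
               calls2[calls2$vaf <= 0.4, ])
})

test_that("expression vetting uses a strict 15-fpkm maximum rule", {
  expect_true(expression_vetting(c(0, 2, 16)))
  expect_false(expression_vetting(c(0, 2, 15)))  # exactly 15 fails
  expect_false(expression_vetting(rep(0, 10)))
  expect_error(expression_vetting(numeric()), "no expression values")
})

test_that("the hematopoiesis rate is exposure per year of age", {
  expect_equal(hsc_rate_per_year(60, 60), 1)
  expect_equal(hsc_rate_per_year(0, 45), 0)
  set.seed(10)
  e <- runif(50, 0, 200); a <- runif(50, 30, 90)
  expect_equal(hsc_rate_per_year(e, a), e / a)
  expect_error(hsc_rate_per_year(10, 0), "positive")
})

test_that("driver mutations assign the highest-priority detection basis", {
  donors <- tibble::tibble(donor_id = c("d1", "d2", "d3", "d4"),
                           age = c(60, 70, 50, 65))
  calls <- tibble::tibble(
    sample_id = c("d1", "d2", "d2", "d3"),
    gene = c("DNMT3A", "PPM1D", "CHEK2", "TET2"),
    consequence = c("missense", "nonsense", "missense", "silent"),
    in_germline_calling = c(TRUE, FALSE, FALSE, FALSE)
  )
  expos <- tibble::tibble(sample_id = donors$donor_id,
                          hsc_exposure = c(60, 35, 10, 5))
  out <- classify_cohort(donors, calls, demo_compendium(), expos)
  expect_equal(out$basis[out$donor_id == "d1"],
               "known_gene_germline_calling")
  # d2 carries both a discovered and a targeted gene: discovered wins
  expect_equal(out$basis[out$donor_id == "d2"], "discovered_gene")
  # silent mutations never count
  expect_false(out$is_CH[out$donor_id == "d3"])
  expect_true(out$is_CH[out$donor_id == "d1"])
})

test_that("the rate rule is strictly greater-than the driver median", {
  donors <- tibble::tibble(donor_id = paste0("d", 1:5),
                           age = rep(50, 5))
  # d1, d2 driver-mutated with rates 1.0 and 2.0 -> median 1.5
  calls <- tibble::tibble(sample_id = c("d1", "d2"),
                          gene = "DNMT3A", consequence = "missense")
  expos <- tibble::tibble(
    sample_id = paste0("d", 1:5),
    hsc_exposure = c(50, 100, 75, 76, 74))  # rates 1, 2, 1.5, 1.52, 1.48
  out <- classify_cohort(donors, calls, demo_compendium(), expos)
  expect_equal(attr(out, "median_rate"), 1.5)
  expect_equal(out$basis[out$donor_id == "d3"], "none")  # exactly median
  expect_equal(out$basis[out$donor_id == "d4"], "rate_threshold")
  expect_equal(out$basis[out$donor_id == "d5"], "none")
  # at most half of driver-mutated donors lie strictly above their median
  drv <- out[out$basis != "rate_threshold" & out$is_CH, ]
  expect_lte(mean(drv$hsc_rate_per_year > attr(out, "median_rate")), 0.5)
})

test_that("classification recovers planted CH truth on a high-signal cohort", {
  cfg <- cohort_config(n_donors = 150, ch_prevalence = 0.3,
                       clone_fraction_range = c(0.5, 0.7),
                       hsc_rate = 2, mean_depth = 60, seed = 29)
  coh <- simulate_cohort(cfg)
  calls <- basic_filters(coh$calls)
  ex <- fit_exposures(catalog_matrix(build_catalog(calls)),
                      as_signature_matrix(hsc_reference_profile()))
  expos <- tibble::tibble(sample_id = ex$sample_id, hsc_exposure = ex$prob)
  comp <- demo_compendium()
  out <- classify_cohort(coh$donors, calls, comp, expos)
  joined <- dplyr::left_join(coh$truth, out, by = "donor_id")
  recall <- mean(joined$is_CH.y[joined$is_CH.x])
  expect_gte(recall, 0.9)
  # cumulative tier counts are non-decreasing
  counts <- ch_tier_counts(out)
  expect_true(all(diff(counts$cumulative) >= 0))
  expect_equal(max(counts$cumulative), sum(out$is_CH))
})

test_that("a cohort without driver mutations skips the rate rule", {
  donors <- tibble::tibble(donor_id = c("d1", "d2"), age = c(50, 60))
  calls <- tibble::tibble(sample_id = character(), gene = character(),
                          consequence = character())
  expos <- tibble::tibble(sample_id = donors$donor_id,
                          hsc_exposure = c(10, 20))
  expect_warning(out <- classify_cohort(donors, calls, demo_compendium(),
                                        expos),
                 "rate-threshold rule skipped")
  expect_false(any(out$is_CH))
})

test_that("co-occurrence equals direct set arithmetic", {
  m <- cbind(g1 = c(1, 1, 0, 0), g2 = c(1, 1, 0, 0),
             g3 = c(0, 0, 1, 0), g4 = c(0, 0, 0, 0))
  rownames(m) <- paste0("d", 1:4)
  cooc <- cooccurrence(m)
  expect_equal(cooc$jaccard[cooc$gene_a == "g1" & cooc$gene_b == "g2"], 1)
  expect_equal(cooc$jaccard[cooc$gene_a == "g1" & cooc$gene_b == "g3"], 0)
  expect_true(is.na(cooc$jaccard[cooc$gene_a == "g3" &
                                   cooc$gene_b == "g4"]))
  set.seed(33)
  mr <- matrix(runif(20 * 6) < 0.3, 20, 6,
               dimnames = list(paste0("d", 1:20), paste0("g", 1:6)))
  got <- cooccurrence(mr)
  for (i in seq_len(nrow(got))) {
    A <- which(mr[, got$gene_a[i]]); B <- which(mr[, got$gene_b[i]])
    uni <- length(union(A, B)); inter <- length(intersect(A, B))
    expect_equal(got$jaccard[i],
                 if (length(A) == 0 || length(B) == 0) NA_real_
                 else inter / uni)
    expect_equal(got$comut_freq[i], inter / 20)
  }
})

test_that("mutation multiplicity is the row-sum histogram", {
  m1 <- diag(5) > 0
  colnames(m1) <- paste0("g", 1:5)
  h1 <- mutation_multiplicity(m1)
  expect_equal(h1$n_genes, 1L)
  expect_equal(h1$fraction, 1)
  expect_equal(nrow(mutation_multiplicity(matrix(FALSE, 3, 2))), 0)
  set.seed(34)
  mr <- matrix(runif(30 * 5) < 0.4, 30, 5)
  got <- mutation_multiplicity(mr)
  rs <- rowSums(mr); rs <- rs[rs >= 1]
  expect_equal(got$n_donors, as.integer(table(rs)))
  expect_equal(sum(got$fraction), 1)
})

test_that("donor-gene matrices respect nonsilent vetting", {
  calls <- tibble::tibble(
    sample_id = c("d1", "d1", "d2"),
    gene = c("TET2", "TET2", "JAK2"),
    consequence = c("missense", "silent", "silent"))
  m <- donor_gene_matrix(calls)
  expect_true(m["d1", "TET2"])
  expect_false(m["d2", "JAK2"])
})
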