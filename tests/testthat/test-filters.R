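test_that("basic filter enforces PASS, read support and the VAF bound", {
  calls <- tibble::tibble(
    sample_id = "s1", chrom = "chr1", pos = 1:5 * 100L,
    ref = "C", alt = "T",
    alt_reads = c(2L, 1L, 10L, 10L, 10L),
    depth = c(10L, 10L, 20L, 20L, 20L),
    vaf = c(0.49, 0.1, 0.5, 0.49, 0.2),
    caller_pass = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  out <- basic_filters(calls)
  # kept: alt_reads >= 2 & PASS & vaf strictly < 0.5
  expect_equal(out$pos, c(100L, 400L))
  # missing read support is rejected with a warning
  calls$alt_reads[1] <- NA
  expect_warning(out2 <- basic_filters(calls), "missing read support")
  expect_equal(out2$pos, 400L)
})

test_that("mask filter honors BED coordinate conventions", {
  calls <- make_calls(1, pos = 100L)
  # 0-based half-open [99, 100) covers 1-based position 100
  expect_equal(nrow(mask_filter(calls, tibble::tibble(
    chrom = "chr1", start = 99L, end = 100L))), 0)
  # [100, 101) does not
  expect_equal(nrow(mask_filter(calls, tibble::tibble(
    chrom = "chr1", start = 100L, end = 101L))), 1)
  # empty mask set returns input unchanged
  expect_identical(mask_filter(calls, NULL), calls)
  # chromosome absent from mask is unmasked
  expect_equal(nrow(mask_filter(calls, tibble::tibble(
    chrom = "chr9", start = 0L, end = 1e6))), 1)
})

test_that("interval overlap equals a naive per-variant scan", {
  set.seed(21)
  for (rep in 1:5) {
    calls <- make_calls(200, chrom = sample(c("chr1", "chr2"), 200,
                                            replace = TRUE))
    masks <- tibble::tibble(
      chrom = sample(c("chr1", "chr2", "chr3"), 40, replace = TRUE),
      start = sample.int(10000L, 40)
    ) |>
      dplyr::mutate(end = start + sample.int(300L, 40))
    kept <- mask_filter(calls, masks)
    oracle_kept <- calls[!naive_mask_hit(calls, masks), ]
    expect_equal(kept, oracle_kept)
  }
})

test_that("adjacent SNVs merge into DBS records left-greedily", {
  calls <- make_calls(2, pos = c(10L, 11L))
  calls$ref <- c("C", "G"); calls$alt <- c("T", "A")
  calls$vaf <- c(0.2, 0.3)
  out <- merge_dbs(calls)
  expect_equal(nrow(out), 1)
  expect_equal(out$ref, "CG")
  expect_equal(out$alt, "TA")
  expect_equal(out$vaf, 0.25)
  expect_equal(out$pos, 10L)
  # non-adjacent positions stay separate
  expect_equal(nrow(merge_dbs(make_calls(2, pos = c(10L, 12L)))), 2)
  # triplets merge left-greedily: one DBS + one SNV
  tri <- merge_dbs(make_calls(3, pos = c(10L, 11L, 12L)))
  expect_equal(nrow(tri), 2)
  expect_equal(nchar(tri$ref), c(2L, 1L))
  expect_equal(tri$pos, c(10L, 12L))
  # different samples never merge
  two <- make_calls(2, pos = c(10L, 11L))
  two$sample_id <- c("a", "b")
  expect_equal(nrow(merge_dbs(two)), 2)
})

test_that("merged record counts match an independent adjacency scan", {
  set.seed(31)
  for (rep in 1:8) {
    calls <- make_calls(120, pos = sample.int(200L, 120),
                        sample_id = sample(c("a", "b"), 120,
                                           replace = TRUE))
    calls <- dplyr::distinct(calls, sample_id, chrom, pos,
                             .keep_all = TRUE)
    out <- merge_dbs(calls)
    pairs <- naive_adjacent_pairs(calls)
    expect_equal(nrow(out), nrow(calls) - pairs)
    expect_equal(sum(nchar(out$ref) == 2), pairs)
  }
})

test_that("frequency filter applies strict resource-specific cutoffs", {
  calls <- make_calls(4, pos = c(10L, 20L, 30L, 40L))
  calls$ref <- "C"; calls$alt <- "T"
  resources <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L),
    ref = "C", alt = "T",
    af = c(4e-04, 0.008, 2e-04),
    resource = c("gnomAD", "PoN_HMF", "gnomAD")
  )
  out <- pon_filter(calls, resources)
  # 4e-4 > 3e-4 gnomAD cutoff -> removed; 0.008 PoN_HMF exactly -> kept
  # (strict); 2e-4 kept; absent from resources -> kept
  expect_equal(out$pos, c(20L, 30L, 40L))
  expect_error(pon_filter(calls, dplyr::mutate(resources,
                                               resource = "mystery")),
               "unknown frequency resource")
})

test_that("the PoN hotspot frequency caps cohort recurrence", {
  calls <- make_calls(3, pos = c(10L, 20L, 30L))
  calls$ref <- "C"; calls$alt <- "T"
  pon <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 99L), ref = "C", alt = "T",
    af = c(0.004, 0.002, 0.003), resource = "PoN_TCGA"
  )
  hotspot <- "chr1:99:C:T"  # hotspot PoN frequency 0.003
  out <- pon_filter(calls, pon, hotspot_keys = hotspot)
  # 0.004 > hotspot 0.003 -> removed; 0.002 <= both cutoffs -> kept
  expect_equal(out$pos, c(20L, 30L))
  # with no resolvable hotspot the threshold falls to 0
  out0 <- pon_filter(calls, pon, hotspot_keys = "chr9:1:A:C")
  expect_equal(out0$pos, 30L)
})

test_that("common SNP filtering is allele-aware", {
  calls <- make_calls(2, pos = c(10L, 20L))
  calls$ref <- "C"; calls$alt <- "T"
  snps <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L), ref = "C",
                         alt = c("T", "G"))
  out <- common_snp_filter(calls, snps)
  # same position different alt allele survives
  expect_equal(out$pos, 20L)
  # random sets: equality with a brute-force membership test
  set.seed(41)
  calls2 <- make_calls(300, pos = sample.int(500L, 300, replace = TRUE))
  snps2 <- make_calls(100, pos = sample.int(500L, 100, replace = TRUE))
  out2 <- common_snp_filter(calls2, snps2[, c("chrom", "pos", "ref", "alt")])
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
  expect_equal(out2, calls2[!(key(calls2) %in% key(snps2)), ])
})

test_that("hypermutator rule removes burdens strictly above the percentile", {
  counts <- setNames(rep(10, 40), paste0("s", 1:40))
  counts["s40"] <- 1000
  expect_equal(hypermutator_cut(counts), "s40")
  # all equal: the percentile equals the common value, strict rule keeps all
  expect_length(hypermutator_cut(setNames(rep(5, 30), paste0("s", 1:30))), 0)
  # 1..1000: equality with a sort-and-interpolate percentile oracle
  counts2 <- setNames(1:1000, paste0("s", 1:1000))
  h <- (1000 - 1) * 0.975 + 1
  thr <- sort(counts2)[floor(h)] + (h - floor(h)) *
    (sort(counts2)[ceiling(h)] - sort(counts2)[floor(h)])
  expect_setequal(hypermutator_cut(counts2),
                  names(counts2)[counts2 > thr])
  expect_warning(hypermutator_cut(c(s1 = 5)), "fewer than 2")
})

test_that("call-set intersection preserves the full set's annotations", {
  full <- make_calls(50, pos = 1:50 * 10L, seed = 51)
  full$gene <- "TET2"
  expect_equal(intersect_callsets(full, full)$pos, full$pos)
  expect_equal(nrow(intersect_callsets(full, full[0, ])), 0)
  set.seed(52)
  other <- full[sample.int(50, 20), c("sample_id", "chrom", "pos", "ref",
                                      "alt")]
  out <- intersect_callsets(full, other, "mutect")
  # nested-loop oracle
  hit <- vapply(seq_len(nrow(full)), function(i) {
    any(other$pos == full$pos[i] & other$ref == full$ref[i] &
          other$alt == full$alt[i] & other$sample_id == full$sample_id[i] &
          other$chrom == full$chrom[i])
  }, logical(1))
  expect_equal(out$pos, full$pos[hit])
  expect_true(all(out$set == "mutect"))
  expect_true(all(out$gene == "TET2"))
})

test_that("a permissive cascade is the identity and reports zero losses", {
  calls <- make_calls(30, pos = 1:30 * 100L, seed = 61,
                      sample_id = rep(c("a", "b", "c"), each = 10))
  res <- run_cascade(calls)
  expect_equal(res$full, calls, ignore_attr = TRUE)
  expect_true(all(tidy(res)$removed == 0))
  expect_equal(res$report$variants_in[-1],
               res$report$variants_out[-nrow(res$report)])
})

test_that("the cascade removes injected germline leakage but keeps clone mutations", {
  cfg <- cohort_config(n_donors = 100, ch_prevalence = 0.5,
                       clone_fraction_range = c(0.3, 0.6),
                       germline_leak_rate = 5, mean_depth = 60, seed = 17)
  coh <- simulate_cohort(cfg)
  res <- germline_frequency_resource(cfg, "gnomAD")
  out <- run_cascade(coh$calls, resources = res)
  key <- function(x) paste(x$sample_id, x$chrom, x$pos, x$ref, x$alt)
  tv <- coh$truth_variants
  leak_keys <- key(tv[tv$origin == "germline", ])
  clone <- dplyr::semi_join(
    coh$calls,
    tv[tv$origin %in% c("hsc", "driver"), ],
    by = c("sample_id", "chrom", "pos", "ref", "alt"))
  clone_keys <- key(clone[clone$alt_reads >= 2 & clone$vaf < 0.5, ])
  surviving <- key(out$full)
  expect_lte(mean(leak_keys %in% surviving), 0.05)
  expect_gte(mean(clone_keys %in% surviving), 0.90)
})

test_that("variant-level filters are individually idempotent", {
  set.seed(71)
  calls <- make_calls(150, pos = sample.int(400L, 150))
  masks <- tibble::tibble(chrom = "chr1", start = c(50L, 200L),
                          end = c(80L, 260L), track = "masked")
  snps <- make_calls(30, pos = sample.int(400L, 30))
  for (f in list(
    basic_filters,
    function(x) mask_filter(x, masks),
    merge_dbs,
    function(x) common_snp_filter(x, snps)
  )) {
    once <- f(calls)
    expect_equal(f(once), once)
  }
})
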