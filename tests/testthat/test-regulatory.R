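consensus_pwm <- function(bases = c("A", "C", "G", "T", "A", "C"),
                          strength = 0.97, background = rep(0.25, 4)) {
  m <- matrix((1 - strength) / 3, length(bases), 4)
  colnames(m) <- c("A", "C", "G", "T")
  for (i in seq_along(bases)) m[i, bases[i]] <- strength
  pwm(m, tf_name = "demoTF", background = background)
}

test_that("PWM construction validates its invariants", {
  m <- matrix(0.25, 4, 4)
  expect_s3_class(pwm(m), "ch_pwm")
  expect_error(pwm(m[1:3, ]), "length >= 4")
  expect_error(pwm(m * 2), "sum to 1")
  expect_error(pwm(m, background = c(0.5, 0.5, 0, 0), pseudocount = 0),
               "pseudocount")
})

test_that("the exact p-value table has the boundary and monotone properties", {
  p <- consensus_pwm()
  tbl <- score_pvalue_table(p)
  # p at the minimum attainable score is 1, above the maximum it is 0
  expect_equal(pwm_pvalue(tbl, tbl$min_score), 1)
  expect_equal(pwm_pvalue(tbl, tbl$max_score + 1L), 0)
  expect_true(all(diff(tbl$table$p_value) <= 1e-12))
  # uniform background: the single best k-mer has probability 4^-k
  expect_equal(pwm_pvalue(tbl, tbl$max_score), 0.25^6)
  # a length-4 motif with one favored base per position: top-score
  # p-value is the probability of the unique consensus k-mer
  p4 <- consensus_pwm(c("A", "C", "G", "T"))
  t4 <- score_pvalue_table(p4)
  expect_equal(pwm_pvalue(t4, t4$max_score), 0.25^4)
})

test_that("the DP distribution equals exhaustive 4^k enumeration", {
  set.seed(201)
  for (len in 4:8) {
    m <- matrix(stats::rgamma(len * 4, 1), len, 4)
    m <- m / rowSums(m)
    bg <- stats::rgamma(4, 2); bg <- bg / sum(bg)
    x <- pwm(m, background = bg)
    tbl <- score_pvalue_table(x)
    oracle <- enumerate_pwm_pvalues(x)
    expect_equal(tbl$table$score, oracle$score)
    expect_equal(tbl$table$prob, oracle$prob, tolerance = 1e-12)
    # oracle p-values: tail sums over enumerated k-mers
    oracle_p <- rev(cumsum(rev(oracle$prob)))
    expect_equal(tbl$table$p_value, oracle_p, tolerance = 1e-12)
  }
})

test_that("variant scanning is strand-symmetric and identity-consistent", {
  x <- consensus_pwm()
  tbl <- score_pvalue_table(x)
  win <- "GGTTACACGTTGGATTACCAGGTTTAACCAA"
  # identical haplotypes give identical p-values
  p_same <- scan_variant(tbl, win, win)
  expect_equal(p_same[["p_ref"]], p_same[["p_alt"]])
  # scanning the reverse complement of both windows changes nothing
  rc <- clonehema:::revcomp(win)
  alt <- sub("ACACGT", "ACTCGT", win)
  p1 <- scan_variant(tbl, win, alt)
  p2 <- scan_variant(tbl, rc, clonehema:::revcomp(alt))
  expect_equal(p1, p2)
  # windows shorter than the motif are skipped
  expect_true(all(is.na(scan_variant(tbl, "ACG", "ACG"))))
})

test_that("a planted consensus match is disrupted by a variant", {
  x <- consensus_pwm()  # consensus ACGTAC
  tbl <- score_pvalue_table(x)
  ref <- "TTTTTTTTTTTTACGTACTTTTTTTTTTTT"
  alt <- sub("ACGTAC", "ACGGAC", ref)
  p <- scan_variant(tbl, ref, alt)
  expect_lt(p[["p_ref"]], p[["p_alt"]])
  # alpha sits between the intact and the broken match p-values
  expect_equal(classify_binding_change(p[["p_ref"]], p[["p_alt"]],
                                       alpha = 1e-3), "disruption")
  # swapping ref and alt maps disruption to creation
  expect_equal(classify_binding_change(p[["p_alt"]], p[["p_ref"]],
                                       alpha = 1e-3), "creation")
})

test_that("scanning with brute force over offsets and strands agrees", {
  set.seed(202)
  x <- consensus_pwm(c("A", "C", "G", "T"))
  tbl <- score_pvalue_table(x)
  for (rep in 1:10) {
    win <- paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
                 collapse = "")
    alt <- win
    substr(alt, 8, 8) <- sample(c("A", "C", "G", "T"), 1)
    got <- scan_variant(tbl, win, alt)
    naive_best <- function(w) {
      best <- -Inf
      for (s in c(w, clonehema:::revcomp(w))) {
        for (off in 1:(nchar(s) - 3)) {
          kmer <- strsplit(substr(s, off, off + 3), "")[[1]]
          sc <- sum(tbl$scores[cbind(1:4, match(kmer, c("A", "C", "G",
                                                        "T")))])
          best <- max(best, sc)
        }
      }
      pwm_pvalue(tbl, best)
    }
    expect_equal(got[["p_ref"]], naive_best(win))
    expect_equal(got[["p_alt"]], naive_best(alt))
  }
})

test_that("the disruption/creation verdict follows the significance table", {
  a <- 1e-4
  expect_equal(classify_binding_change(5e-5, 0.3, a), "disruption")
  expect_equal(classify_binding_change(0.3, 5e-5, a), "creation")
  expect_equal(classify_binding_change(5e-5, 5e-5, a), "none")
  expect_equal(classify_binding_change(0.3, 0.3, a), "none")
  # boundary: exactly alpha is not significant
  expect_equal(classify_binding_change(a, 0.3, a), "none")
  expect_equal(classify_binding_change(0.99e-4, a, a), "disruption")
})

test_that("the regulatory worklist equals a brute-force triple filter", {
  set.seed(203)
  calls <- make_calls(120, pos = sample.int(5000L, 120))
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(0L, 2000L), end = c(1000L, 3500L))
  enh <- tibble::tibble(
    chrom = "chr1",
    start = seq(0L, 4500L, by = 500L),
    end = seq(400L, 4900L, by = 500L),
    target_gene = c("TET2", NA, "GNAS", "DNMT3A", NA, "TET2", "JAK2",
                    "OTHER", "GNAS", "TET2"))
  comp <- c("TET2", "DNMT3A", "JAK2")
  got <- filter_regulatory_context(calls, peaks, enh, comp)
  # naive scan
  expected <- integer()
  for (i in seq_len(nrow(calls))) {
    p0 <- calls$pos[i] - 1
    in_peak <- any(peaks$start <= p0 & p0 < peaks$end)
    hits <- which(enh$start <= p0 & p0 < enh$end &
                    !is.na(enh$target_gene) & enh$target_gene %in% comp)
    if (in_peak && length(hits) > 0) expected <- c(expected, i)
  }
  expect_equal(got$pos, calls$pos[expected])
  expect_equal(attr(got, "unannotated_enhancers"), 2)
  # mutations outside all peaks and non-compendium targets are gone
  expect_true(all(got$target_gene %in% comp))
})

test_that("MEME motifs round-trip through the parser", {
  path <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.3 C 0.2 G 0.2 T 0.3", "",
    "MOTIF RARA_demo",
    "letter-probability matrix: alength= 4 w= 5 nsites= 20 E= 0",
    " 0.80 0.10 0.05 0.05",
    " 0.05 0.80 0.10 0.05",
    " 0.05 0.10 0.80 0.05",
    " 0.05 0.05 0.10 0.80",
    " 0.25 0.25 0.25 0.25"
  ), path)
  pwms <- read_meme(path)
  expect_named(pwms, "RARA_demo")
  x <- pwms$RARA_demo
  expect_equal(nrow(x$matrix), 5)
  expect_equal(unname(x$background), c(0.3, 0.2, 0.2, 0.3))
  expect_equal(unname(x$matrix[1, "A"]), 0.8)
})

test_that("binding-event scanning labels planted events end to end", {
  genome <- list(chr1 = paste0(
    paste(rep("T", 50), collapse = ""), "ACGTAC",
    paste(rep("T", 50), collapse = "")))
  worklist <- tibble::tibble(
    chrom = "chr1", pos = 54L, ref = "T", alt = "G",
    target_gene = "TET2")
  pwms <- list(demoTF = consensus_pwm())
  out <- scan_binding_events(worklist, pwms, genome, alpha = 1e-3)
  expect_equal(out$verdict, "disruption")
  expect_equal(out$target_gene, "TET2")
})
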