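# Synthetic paired blood/tumor cohorts.
#
# The generator emulates the statistical structure the CH analysis assumes:
# age-dependent accumulation of HSC-signature mutations amplified by a clonal
# expansion, a driver mutation at a hotspot locus with hitchhiking
# passengers at clone-determined VAF, germline-variant leakage present in
# both the blood and the tumor call set, and concentrated artifact
# signatures. Ground truth is carried separately from the emitted call sets
# so recovery tests are honest.

CHROM_LEVELS <- paste0("chr", 1:22)

default_driver_genes <- function() {
  # hotspot loci are named placeholders exercising hotspot-dependent
  # filters; coordinates are synthetic
  tibble::tibble(
    gene  = c("DNMT3A", "JAK2", "TET2", "ASXL1", "PPM1D", "CHEK2"),
    chrom = c("chr2", "chr9", "chr4", "chr20", "chr17", "chr22"),
    pos   = c(25234373L, 5073770L, 105235684L, 32434638L, 60663081L,
              28695868L),
    ref   = c("C", "G", "C", "C", "C", "G"),
    alt   = c("T", "T", "T", "A", "T", "A"),
    label = c("R882H", "V617F", "Q1523*", "G646fs", "R552*", "T367fs")
  )
}

#' Configuration of a synthetic paired blood/tumor cohort
#'
#' Fixes the generative conditions of a cohort: donor count and age range,
#' CH prevalence, the rate at which detectable HSC-signature mutations
#' accumulate per year of age in a CH clone, the clone-fraction range,
#' sequencing depth, germline leakage and artifact burdens, and the driver
#' hotspot table. A fixed `seed` makes the cohort byte-identical across
#' runs.
#'
#' @param n_donors Number of donors.
#' @param age_range Length-2 numeric, donor ages sampled uniformly (years).
#' @param ch_prevalence Probability a donor carries a CH clone, in \[0, 1\].
#' @param hsc_rate Detectable HSC-signature mutations contributed per year
#'   of age by the clone of a CH donor.
#' @param clone_fraction_range Length-2 numeric in (0, 1\]; clone cell
#'   fractions are sampled uniformly in this range. Heterozygous clone
#'   mutations then sit at true VAF `clone_fraction / 2`.
#' @param mean_depth Mean sequencing depth; per-variant depth is
#'   Poisson(`mean_depth`) and alternate reads Binomial(depth, true VAF).
#' @param germline_leak_rate Expected number of germline variants leaking
#'   into a donor's somatic call set (Poisson), drawn from a cohort-shared
#'   pool of common polymorphic sites.
#' @param artifact_burden_range Length-2 numeric; per-donor mutation burden
#'   of each artifact signature is sampled uniformly in this range.
#' @param driver_genes Tibble of hotspot loci
#'   (`gene`, `chrom`, `pos`, `ref`, `alt`, `label`).
#' @param seed Integer master seed.
#' @return A validated list of class `ch_cohort_config`.
#' @export
cohort_config <- function(n_donors = 200,
                          age_range = c(40, 80),
                          ch_prevalence = 0.15,
                          hsc_rate = 1.0,
                          clone_fraction_range = c(0.1, 0.6),
                          mean_depth = 40,
                          germline_leak_rate = 3,
                          artifact_burden_range = c(5, 30),
                          driver_genes = default_driver_genes(),
                          seed = 1L) {
  stopifnot(n_donors >= 1, length(age_range) == 2, age_range[1] > 0,
            age_range[1] <= age_range[2])
  if (ch_prevalence < 0 || ch_prevalence > 1) {
    rlang::abort("ch_prevalence must lie in [0, 1]")
  }
  if (clone_fraction_range[1] <= 0 || clone_fraction_range[2] > 1 ||
      clone_fraction_range[1] > clone_fraction_range[2]) {
    rlang::abort("clone fractions must lie in (0, 1]")
  }
  if (mean_depth < 1) rlang::abort("mean_depth must be >= 1")
  if (germline_leak_rate < 0) rlang::abort("germline_leak_rate must be >= 0")
  assert_calls(driver_genes, c("gene", "chrom", "pos", "ref", "alt"))
  structure(list(
    n_donors = as.integer(n_donors), age_range = age_range,
    ch_prevalence = ch_prevalence, hsc_rate = hsc_rate,
    clone_fraction_range = clone_fraction_range, mean_depth = mean_depth,
    germline_leak_rate = germline_leak_rate,
    artifact_burden_range = artifact_burden_range,
    driver_genes = driver_genes, seed = as.integer(seed)
  ), class = "ch_cohort_config")
}

donor_seed <- function(config, donor_index, salt = 0L) {
  as.integer((config$seed + 7919 * donor_index + salt) %%
               .Machine$integer.max)
}

#' Sample mutation records from a 96-channel signature profile
#'
#' Draws `n` single-base substitutions whose channel counts follow a
#' multinomial on the profile, optionally reweighted by per-channel genome
#' availability. Each record is placed at a random locus on a synthetic
#' genome; with probability one half the record is emitted on the purine
#' strand (context and alleles reverse-complemented) so downstream strand
#' collapsing is exercised.
#'
#' @param profile Tibble with `channel`/`prob` columns (or a numeric
#'   vector of length 96 in channel order). Must be non-negative and sum
#'   to 1 within 1e-6.
#' @param n Number of mutations to draw.
#' @param context_weights Optional numeric vector of length 96 of relative
#'   channel availability (defaults to uniform).
#' @param seed Optional integer; if given, the draw is reseeded.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `context`, `channel`,
#'   exactly `n` rows.
#' @export
sample_mutations_from_signature <- function(profile, n, context_weights = NULL,
                                            seed = NULL) {
  p <- if (is.data.frame(profile)) {
    profile$prob[match(sbs96_channels(), profile$channel)]
  } else {
    as.numeric(profile)
  }
  if (length(p) != 96 || anyNA(p)) rlang::abort("profile must cover 96 channels")
  if (any(p < 0)) rlang::abort("profile has negative entries")
  if (abs(sum(p) - 1) > 1e-6) rlang::abort("profile must sum to 1")
  if (n < 0) rlang::abort("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          context = character(), channel = character()))
  }
  w <- p * (context_weights %||% rep(1, 96))
  if (sum(w) == 0) rlang::abort("profile x context weights is all zero")
  counts <- as.integer(rmultinom(1, n, w / sum(w)))
  channel <- rep(sbs96_channels(), counts)
  channel <- channel[sample.int(n)]
  parts <- channel_parts(channel)
  flip <- runif(n) < 0.5
  ctx <- parts$context
  ref <- parts$ref
  alt <- parts$alt
  ctx[flip] <- revcomp(ctx[flip])
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  tibble::tibble(
    chrom = sample(CHROM_LEVELS, n, replace = TRUE),
    pos = sample.int(100000000L, n, replace = TRUE),
    ref = ref, alt = alt, context = ctx, channel = channel
  )
}

# Cohort-shared pool of common polymorphic sites from which germline
# leakage is drawn; deterministic in the config seed.
germline_site_pool <- function(config, n_sites = 200) {
  set.seed(donor_seed(config, 0L, salt = 104729L))
  base <- sample_mutations_from_signature(
    rep(1 / 96, 96), n_sites)
  base$maf <- runif(n_sites, 0.05, 0.5)
  base
}

add_read_support <- function(records, vaf_true, mean_depth) {
  n <- nrow(records)
  depth <- pmax(rpois(n, mean_depth), 1L)
  alt_reads <- rbinom(n, depth, vaf_true)
  records$alt_reads <- as.integer(alt_reads)
  records$depth <- as.integer(depth)
  records$vaf <- alt_reads / depth
  records
}

#' Simulate one donor of a synthetic cohort
#'
#' A CH donor (probability `ch_prevalence`) receives a clone: one driver
#' mutation at a hotspot locus plus a Poisson(`age * hsc_rate`) number of
#' hitchhiking HSC-signature passengers, all at true VAF
#' `clone_fraction / 2` with binomial read sampling. Every donor receives
#' artifact-signature variants at low VAF and Poisson-distributed germline
#' leakage drawn from the cohort-shared common-site pool; leakage appears
#' in both the blood and the tumor call set, true somatic variants in the
#' blood set only.
#'
#' @param config A [cohort_config()].
#' @param donor_index 1-based donor index (also seeds the donor).
#' @return List with `donor` (metadata row), `calls` (blood call tibble),
#'   `tumor_calls`, `truth` (donor-level ground truth) and
#'   `truth_variants` (per-variant origin).
#' @export
simulate_donor <- function(config, donor_index) {
  stopifnot(inherits(config, "ch_cohort_config"))
  pool <- germline_site_pool(config)
  set.seed(donor_seed(config, donor_index))
  id <- sprintf("D%04d", donor_index)
  age <- round(runif(1, config$age_range[1], config$age_range[2]))
  sex <- sample(c("male", "female"), 1)
  cancer_type <- sample(c("breast", "colorect", "lung", "prostate", "skin"), 1)
  cytotoxic <- runif(1) < 0.35
  platinum <- cytotoxic && runif(1) < 0.5
  non_cytotoxic <- runif(1) < 0.4
  is_ch <- runif(1) < config$ch_prevalence

  hsc <- hsc_reference_profile()
  blood <- list()
  origin <- character()
  driver_gene <- NA_character_
  clone_fraction <- NA_real_
  n_hsc <- 0L

  if (is_ch) {
    clone_fraction <- runif(1, config$clone_fraction_range[1],
                            config$clone_fraction_range[2])
    vaf_true <- clone_fraction / 2
    drv <- config$driver_genes[sample.int(nrow(config$driver_genes), 1), ]
    driver_gene <- drv$gene
    driver_rec <- tibble::tibble(
      chrom = drv$chrom, pos = as.integer(drv$pos), ref = drv$ref,
      alt = drv$alt,
      context = paste0("A", drv$ref, "A"),
      channel = sbs96_channel(paste0("A", drv$ref, "A"), drv$ref, drv$alt)
    )
    driver_rec <- add_read_support(driver_rec, vaf_true, config$mean_depth)
    driver_rec$gene <- drv$gene
    driver_rec$consequence <- "missense"
    n_hsc <- rpois(1, age * config$hsc_rate)
    pass <- sample_mutations_from_signature(hsc, n_hsc)
    pass <- add_read_support(pass, vaf_true, config$mean_depth)
    pass$gene <- NA_character_
    pass$consequence <- "noncoding"
    blood <- c(blood, list(driver_rec, pass))
    origin <- c(origin, "driver", rep("hsc", n_hsc))
  }

  for (which in c("oxidative", "noise")) {
    burden <- round(runif(1, config$artifact_burden_range[1],
                          config$artifact_burden_range[2]))
    art <- sample_mutations_from_signature(artifact_profile(which), burden)
    art <- add_read_support(art, runif(burden, 0.02, 0.2),
                            config$mean_depth)
    art$gene <- NA_character_
    art$consequence <- "noncoding"
    blood <- c(blood, list(art))
    origin <- c(origin, rep(paste0("artifact_", which), burden))
  }

  n_leak <- rpois(1, config$germline_leak_rate)
  n_leak <- min(n_leak, nrow(pool))
  leak <- pool[sample.int(nrow(pool), n_leak), , drop = FALSE]
  leak <- leak[, c("chrom", "pos", "ref", "alt", "context", "channel")]
  leak <- add_read_support(leak, 0.5, config$mean_depth)
  leak$gene <- NA_character_
  leak$consequence <- "noncoding"
  blood <- c(blood, list(leak))
  origin <- c(origin, rep("germline", n_leak))

  calls <- dplyr::bind_rows(blood)
  calls$caller_pass <- TRUE
  calls$sample_id <- id
  calls$origin <- origin
  calls <- dplyr::arrange(calls, factor(.data$chrom, levels = CHROM_LEVELS),
                          .data$pos)
  truth_variants <- calls[, c("sample_id", "chrom", "pos", "ref", "alt",
                              "origin")]
  calls$origin <- NULL
  calls <- calls[, c("sample_id", "chrom", "pos", "ref", "alt", "alt_reads",
                     "depth", "vaf", "caller_pass", "context", "gene",
                     "consequence")]

  tumor_calls <- calls[paste(calls$chrom, calls$pos, calls$ref, calls$alt) %in%
                         paste(leak$chrom, leak$pos, leak$ref, leak$alt), ]

  list(
    donor = tibble::tibble(
      donor_id = id, age = age, sex = sex, cancer_type = cancer_type,
      cytotoxic = cytotoxic, platinum = platinum,
      non_cytotoxic = non_cytotoxic, cohort = "metastasis"
    ),
    calls = calls,
    tumor_calls = tumor_calls,
    truth = tibble::tibble(
      donor_id = id, is_CH = is_ch, driver_gene = driver_gene,
      clone_fraction = clone_fraction, n_hsc_true = n_hsc
    ),
    truth_variants = truth_variants
  )
}

#' Simulate a full synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return Object of class `ch_cohort`: tibbles `donors`, `calls` (blood),
#'   `tumor_calls`, `truth`, `truth_variants`, plus the `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_donors = 5, seed = 7))
#' cohort$donors
simulate_cohort <- function(config) {
  sims <- purrr::map(seq_len(config$n_donors),
                     function(i) simulate_donor(config, i))
  structure(list(
    donors = purrr::map_dfr(sims, "donor"),
    calls = purrr::map_dfr(sims, "calls"),
    tumor_calls = purrr::map_dfr(sims, "tumor_calls"),
    truth = purrr::map_dfr(sims, "truth"),
    truth_variants = purrr::map_dfr(sims, "truth_variants"),
    config = config
  ), class = "ch_cohort")
}

#' @export
print.ch_cohort <- function(x, ...) {
  cat(sprintf("<ch_cohort> %d donors, %d blood calls, %d tumor calls\n",
              nrow(x$donors), nrow(x$calls), nrow(x$tumor_calls)))
  cat(sprintf("  CH truth: %d/%d donors\n", sum(x$truth$is_CH),
              nrow(x$truth)))
  invisible(x)
}

#' Frequency resources implied by the cohort's germline pool
#'
#' Builds a panel-of-normals-style frequency table from the cohort-shared
#' germline site pool (site minor allele frequencies under a chosen
#' resource label), used to test that the filter cascade removes injected
#' germline leakage.
#'
#' @param config A [cohort_config()].
#' @param resource Resource label stamped on the rows.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `af`, `resource`.
#' @export
germline_frequency_resource <- function(config, resource = "gnomAD") {
  pool <- germline_site_pool(config)
  tibble::tibble(chrom = pool$chrom, pos = pool$pos, ref = pool$ref,
                 alt = pool$alt, af = pool$maf, resource = resource)
}

#' Simulate a planted-mixture SBS96 catalog
#'
#' Benchmark cohort for signature extraction: each sample's mutations are
#' drawn from a mixture of the synthetic HSC reference profile and the two
#' artifact profiles. The HSC share varies per sample uniformly in
#' `hsc_share` (mean 70%), and the remaining burden is split uniformly at
#' random between the two artifact profiles; the per-sample variation in
#' mixing proportions is what renders the factorization identifiable.
#' Mutation records are materialized via
#' [sample_mutations_from_signature()] and counted with [build_catalog()].
#'
#' @param n_samples Number of samples.
#' @param total_range Integer range of per-sample mutation totals
#'   (uniform).
#' @param hsc_share Length-2 numeric range of the per-sample HSC mixture
#'   share.
#' @param seed Integer seed.
#' @return List with `catalog` (wide tibble), `profiles` (96 x 3 matrix of
#'   the planted HSC and artifact profiles) and `shares` (per-sample
#'   mixing proportions).
#' @export
simulate_signature_catalog <- function(n_samples = 300,
                                       total_range = c(150, 500),
                                       hsc_share = c(0.55, 0.85),
                                       seed = 1L) {
  set.seed(as.integer(seed))
  profiles <- cbind(
    HSC = as_signature_matrix(hsc_reference_profile())[, 1],
    artifact_ox = as_signature_matrix(artifact_profile("oxidative"))[, 1],
    artifact_noise = as_signature_matrix(artifact_profile("noise"))[, 1]
  )
  shares <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    total = sample(seq(total_range[1], total_range[2]), n_samples,
                   replace = TRUE),
    hsc = runif(n_samples, hsc_share[1], hsc_share[2]),
    split = runif(n_samples)
  )
  calls <- purrr::map_dfr(seq_len(n_samples), function(i) {
    w <- c(shares$hsc[i],
           (1 - shares$hsc[i]) * shares$split[i],
           (1 - shares$hsc[i]) * (1 - shares$split[i]))
    n_per <- as.integer(rmultinom(1, shares$total[i], w))
    recs <- purrr::map2_dfr(seq_len(3), n_per, function(p, np) {
      sample_mutations_from_signature(profiles[, p], np)
    })
    recs$sample_id <- shares$sample_id[i]
    recs
  })
  list(catalog = build_catalog(calls), profiles = profiles,
       shares = shares)
}
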