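# Packaged 96-channel reference profiles.
#
# The healthy-donor whole-genome catalogs behind the published HSC signature
# are protected data; the profile shipped here is SYNTHETIC: a clock-like
# stand-in built in code with the qualitative features of mutation
# accumulation in hematopoietic stem cells (a broad, flat T>C / C>T dominated
# spectrum with elevated C>T at NpCpG contexts). It is the generative truth
# for the synthetic-cohort module and the recovery target for the signature
# extraction tests, not a measurement.

#' Synthetic hematopoietic stem cell (HSC) reference signature
#'
#' A deterministic, code-generated 96-channel probability profile emulating
#' the clock-like spectrum of mutations accumulated during normal HSC
#' divisions: broad T>C and C>T activity with elevated C>T at NpCpG
#' (deamination-like) contexts and low weight elsewhere. Synthetic — it
#' stands in for a signature measured on healthy-donor genomes, which are
#' protected data.
#'
#' @return A tibble with columns `channel` (SBS96 label) and `prob`,
#'   summing to 1.
#' @export
#' @examples
#' prof <- hsc_reference_profile()
#' sum(prof$prob)
hsc_reference_profile <- function() {
  ch <- sbs96_channels()
  parts <- channel_parts(ch)
  w <- numeric(96)
  sub <- paste0(parts$ref, ">", parts$alt)
  # broad clock-like body
  w[sub == "T>C"] <- 3.0
  w[sub == "C>T"] <- 2.0
  w[sub == "T>A"] <- 0.7
  w[sub == "C>A"] <- 0.6
  w[sub == "C>G"] <- 0.4
  w[sub == "T>G"] <- 0.5
  # CpG deamination spike on C>T
  cpg <- sub == "C>T" & substr(parts$context, 3, 3) == "G"
  w[cpg] <- w[cpg] * 4
  # mild, deterministic context ripple so channels are not exactly tied
  w <- w * (1 + 0.15 * sin(seq_len(96)))
  tibble::tibble(channel = ch, prob = w / sum(w))
}

#' Synthetic artifact signature profiles
#'
#' Two concentrated, code-generated 96-channel profiles used to contaminate
#' synthetic cohorts: an oxidative-damage-like profile (all weight on C>A
#' channels, context-skewed) and a sequencing-noise-like profile (weight on
#' T>A and T>G channels). Both are nearly orthogonal to
#' [hsc_reference_profile()] (pairwise cosine < 0.4), which is what makes
#' signature-recovery tests informative.
#'
#' @param which `"oxidative"` or `"noise"`.
#' @return A tibble with columns `channel` and `prob`, summing to 1.
#' @export
#' @examples
#' cosine_similarity(artifact_profile("oxidative")$prob,
#'                   hsc_reference_profile()$prob)
artifact_profile <- function(which = c("oxidative", "noise")) {
  which <- match.arg(which)
  ch <- sbs96_channels()
  parts <- channel_parts(ch)
  sub <- paste0(parts$ref, ">", parts$alt)
  w <- numeric(96)
  if (which == "oxidative") {
    w[sub == "C>A"] <- 1
    # 8-oxo-G-like skew towards CCG/GCA style contexts
    skew <- sub == "C>A" & substr(parts$context, 1, 1) %in% c("C", "G")
    w[skew] <- 4
  } else {
    w[sub == "T>A"] <- 2
    w[sub == "T>G"] <- 1
    skew <- sub == "T>G" & substr(parts$context, 3, 3) == "T"
    w[skew] <- 5
  }
  w <- w * (1 + 0.2 * cos(seq_len(96) / 3))
  tibble::tibble(channel = ch, prob = w / sum(w))
}
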