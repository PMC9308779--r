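---
title: "Methods: detecting clonal hematopoiesis from reverse somatic calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting clonal hematopoiesis from reverse somatic calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(clonehema)
```

## The model

Clonal hematopoiesis (CH) is the expansion of a hematopoietic stem cell
(HSC) clone carrying a selectively advantageous somatic mutation. The
package analyzes *reverse* somatic calls — the blood sample treated as
the tumor, the patient's solid tumor as the germline reference — which
isolate mutations private to the hematopoietic compartment. Three layers
of signal are assumed:

1. **A driver mutation** in a CH gene, present in the whole clone. For a
   heterozygous mutation in a clone occupying cell fraction `f`, the
   expected variant allele frequency (VAF) is `f/2`.
2. **Hitchhiking passengers**: mutations acquired at a roughly constant
   rate per HSC division before the expansion, amplified to the same VAF
   as the driver. Their number grows with donor age, and their spectrum
   follows the clock-like HSC mutational signature; hence the *rate of
   hematopoiesis mutations per year of age* (HSC-signature exposure
   divided by age) separates expanded from unexpanded samples.
3. **Noise**: germline variants leaking through the calling (present in
   both blood and tumor, recurrent across donors at population allele
   frequencies), and sequencing artifacts with concentrated trinucleotide
   spectra.

The filter cascade removes layer 3, the signature machinery quantifies
layer 2, and classification combines driver genes (layer 1) with the
rate rule (layer 2).

## Filter cascade

Steps, in order: caller PASS with at least two supporting reads and
VAF strictly below 0.5; low-mappability mask; merging of adjacent
same-sample SNVs into double-base substitutions; panel-of-normals and
population-frequency filters; common-SNP exclusion; segmental
duplication / simple repeat / masked-region filters; exclusion of
samples whose mutation count exceeds the 97.5th percentile of the cohort
burden. Every step returns a subset of its input and the cascade records
a per-step ledger (`tidy()` on the result).

Numerical conventions that matter:

* All frequency comparisons are strict ("greater than"); ties are kept.
  The population cutoffs default to 0.002 (PoN TCGA), 0.008 (PoN HMF)
  and 0.0003 (gnomAD). When hotspot keys are supplied, a PoN resource
  additionally removes variants strictly more frequent than the most
  frequent of those hotspots — the rationale being that a *bona fide* CH
  hotspot marks the highest cohort frequency a genuinely somatic variant
  attains. With no hotspot keys the hotspot rule is inactive rather than
  degenerating to a zero threshold.
* Internal mask arithmetic is 0-based half-open (BED); variant positions
  are 1-based (VCF). Masks are merged before a `findInterval()` sweep; a
  brute-force per-variant scan is the test oracle.
* DBS merging is left-greedy over runs of adjacent positions (a triplet
  yields one DBS plus one trailing SNV), deterministic on sorted input.
  The merged record keeps the first position, concatenated alleles and
  the mean VAF of the pair.
* The hypermutator percentile is the linear-interpolation sample
  quantile (R type 7). This rule is applied once per cascade run. It is
  worth being explicit about a limitation: a strict "above the
  percentile" rule is not a mathematical fixpoint — on any cohort whose
  burdens are distinct, re-running it repeatedly would keep trimming the
  upper tail. The cascade is therefore idempotent on burden-tied cohorts
  (and trivially whenever the rule removes nothing), which is how the
  property-based tests exercise it; the rule itself is a one-shot
  cohort-cleaning step, not an iterated operator.
* On synthetic cohorts the highest-burden samples are disproportionately
  CH donors (passenger load scales with age × rate), so the hypermutator
  rule can remove a true CH donor — the same conservative trade-off the
  real rule makes.

## SBS96 catalogs and signatures

Catalogs count single-base substitutions into the 96 pyrimidine-centric
channels (six substitution classes × 16 flanking-base contexts);
purine-reference variants are reverse-complemented. The catalog total
always equals the number of usable SNVs; non-SNVs and unresolvable
contexts are counted as skipped.

De novo extraction is bootstrapped NMF:

* **Objective**: generalized Kullback–Leibler divergence with
  multiplicative updates, the convention of the signature-extraction
  literature; the objective is non-increasing across updates (asserted
  per-iteration in tests on small instances). A Frobenius objective is
  available behind a flag. Convergence: relative objective change below
  `tol = 1e-6`, capped at `max_iter = 400` updates; non-convergence
  returns the best iterate and flags the result.
* **Bootstrap**: each sample's catalog is resampled multinomially at its
  own total; 100 bootstraps by default; per-bootstrap seeds derive from
  the master seed and the (rank, bootstrap) indices.
* **Consensus**: per-bootstrap signature solutions are matched to
  running centroids by greedy one-to-one cosine assignment; the
  consensus signatures are the centroids, renormalized to probabilities.
  Cluster quality is the mean silhouette on cosine distance.
* **Rank selection**: among candidate ranks whose mean silhouette is
  within `stability_margin = 0.9` of the best rank's, the rank with the
  lowest reconstruction error is chosen. Plain silhouette maximization
  was rejected because it systematically under-fits: merging two true
  signatures still produces tight bootstrap clusters, so the collapsed
  rank out-silhouettes the true one while fitting the data worse. The
  adopted rule reads as "as many signatures as remain stable".
* **Exposures**: non-negative least squares of each original catalog on
  the consensus signatures, so exposures are in mutation counts;
  near-collinear signature sets (pairwise cosine > 0.999) are flagged.
  No sparsity penalty is applied.
* Samples with more than 100 mutations enter the extraction (strictly
  more; a total of exactly 100 is excluded).

The packaged HSC reference profile is **synthetic**: a deterministic,
clock-like 96-channel profile (broad T>C / C>T body, C>T elevated at
NpCpG) built in code, standing in for a signature measured on protected
healthy-donor genomes. The two packaged artifact profiles (oxidative
C>A-concentrated; T>A/T>G noise) have cosine < 0.4 to the HSC profile,
which is what makes recovery benchmarks informative.

## CH classification

Donors with a nonsilent mutation (missense, nonsense, frameshift,
splice, in-frame indel) in a compendium gene are CH cases; the basis
label follows the tier of the gene and the calling provenance, in the
cumulative order: known gene seen by germline calling, known gene by
reverse calling, discovered gene, targeted-cohort gene. The median rate
of hematopoiesis mutations per year of age across these driver-mutated
donors then defines the rate rule: remaining donors are cases iff their
rate is *strictly greater* than that median (a donor exactly at the
median is not called). If the compendium distinguishes cohorts, the
median should be computed per cohort; the function operates on whatever
donor set it is given, which makes the per-cohort choice explicit at the
call site.

## Associations

CH status is modeled by maximum-likelihood logistic regression on age in
years (untransformed, so coefficients are per-year log-odds), sex, and
cytotoxic / non-cytotoxic treatment indicators, with Wald 95% intervals.
Degenerate outcomes and perfect separation are flagged and the
coefficient table withheld rather than reported. Gene-level treatment
models (mutated yes/no ~ treatment + age + sex) are corrected by
Benjamini–Hochberg FDR within each treatment family; genes mutated in
fewer than five donors are skipped. The treatment taxonomy (what counts
as cytotoxic, platinum as a sub-family) is supplied with the metadata
rather than hard-coded.

## Motif scanning

The transcription-factor machinery follows the FIMO convention: PWM
cells get a pseudocount (default 0.001) and are converted to log2
likelihood ratios against an order-0 background (configurable
frequencies; uniform by default). Scores are quantized per position to
integer multiples of `granularity = 1e-3` log2-odds units, and the exact
null distribution of the total quantized score is computed by
dynamic-programming convolution over positions — so p-values,
`P(score >= s)` under the background, are exact to the granularity, and
the same per-position quantization is used when scoring windows, making
table lookups exact rather than approximate. Tests verify the DP against
exhaustive 4^k enumeration for motif lengths up to 8.

A variant is scanned on the reference haplotype window (±15 bp) and on
the same window with the alternate base substituted, over all offsets
and both strands; each haplotype's p-value is the minimum over offsets
and strands. The verdict at `alpha = 1e-4`: *disruption* iff the
reference is significant and the alternate is not; *creation* in the
opposite case; otherwise *none* (including both-significant and
neither-significant). Motif objects require length ≥ 4 — a genuine
binding model is never shorter — so the degenerate single-base
sanity check appears in tests as its length-4 analog (the consensus
k-mer of a 4-long motif has p = 4^-4 under a uniform background).

Only mutations inside both an H3K27ac peak and an enhancer whose
annotated target gene is in the driver compendium are scanned, and only
against motifs of TFs expressed in the reference cell population
(strictly above 15 fpkm at the distribution maximum). The enhancer's
annotated target is trusted; no independent nearest-gene computation is
attempted.

## The synthetic cohort generator

The generator fixes the study conditions for every recovery test:

| parameter | default | rationale |
|---|---|---|
| `n_donors` | 200 | desk-scale cohort |
| `age_range` | 40–80 y | adult cancer cohort |
| `ch_prevalence` | 0.15 | order of reported CH case rates in such cohorts |
| `hsc_rate` | 1 mutation/year | detectable passengers scale with age; keeps a 60-year-old's clone near the ~100-mutation floor of extraction |
| `clone_fraction_range` | 0.1–0.6 | VAFs 0.05–0.3, spanning the detectable range below the 0.5 filter |
| `mean_depth` | 40 reads | typical whole-genome depth; the real cohorts' depth is not public, so this is a free parameter |
| `germline_leak_rate` | 3/donor | enough leakage to exercise the frequency filters |
| `artifact_burden_range` | 5–30 | artifact burden comparable to clone burden, so filters are load-bearing |

Read support is Binomial(depth, true VAF) with depth ~ Poisson
(`mean_depth`) — the simplest bulk-sequencing model. Trinucleotide
context availability is uniform (no reference genome required); emitted
records randomly choose a strand so that catalog construction must
collapse strands. Germline leakage is drawn from a cohort-shared pool of
200 common polymorphic sites with population frequencies in 0.05–0.5,
which is also what `germline_frequency_resource()` exposes as a
PoN/gnomAD-style table. Driver hotspots default to named loci imitating
recurrent CH hotspots (the coordinates are synthetic). Ground truth
(donor CH status, clone fraction, per-variant origin) is stored apart
from the emitted VCFs, so recovery tests cannot leak it.

The planted-mixture benchmark (`simulate_signature_catalog()`) draws
300 samples of 150–500 mutations with a per-sample HSC share uniform in
0.55–0.85 (mean ≈ 0.7) and the remainder split uniformly between the two
artifact profiles. The per-sample variation in mixing proportions is
essential: with identical shares the expected catalog is rank-1 and no
factorization method could separate the components.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: read-level errors and mapping
artifacts (read support is drawn, not aligned); mosaic chromosomal
alterations; correlation between treatment exposure and CH emergence
(prevalence is flat in covariates, so association tests build their own
planted-effect simulations); realistic genome context availability; and
multi-clone architectures (one clone per donor).

## Problem sizes

The test suite and the acceptance script run at sizes chosen to make the
statistics meaningful on a single CPU: 300-sample extraction benchmarks
at 100 bootstraps and k ∈ {2,3,4}; recovery and classification cohorts
of 100–250 donors; 100-replicate calibration of the logistic model at
n = 2000; 1,000 cascade fuzz inputs; exhaustive PWM enumeration up to
length 8.

## Known limitations

* The consensus clustering matches solutions greedily to running
  centroids; with many near-degenerate signatures a global assignment
  (Hungarian) could differ. At the ranks used here the greedy and global
  assignments coincide in practice.
* NNLS attribution of exposures is unregularized; strongly correlated
  signatures will split exposure unstably (flagged, not resolved).
* The hypermutator rule's non-idempotence is inherent to a strict
  percentile cutoff (discussed above).
* `classify_cohort()` trusts the `consequence` annotation; functional
  annotation itself is out of scope.
* Binding-change scanning handles substitutions only; indels in motif
  windows are not scored.
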