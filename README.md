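# clonehema

Detection of clonal hematopoiesis (CH) from paired blood/tumor somatic
variant calls.

## The problem

Clonal hematopoiesis is the age-related expansion of a hematopoietic stem
cell (HSC) clone carrying a selectively advantageous somatic mutation. In
cancer cohorts, blood is usually sequenced only as the *germline control*
for the tumor — at depths where subclonal blood mutations are hard to
separate from sequencing error, and where calling somatic mutations on the
blood alone misclassifies germline variants. The trick this package
implements is **reverse calling**: treat the blood sample as the "tumor"
and the patient's solid tumor as the germline reference, so that variants
private to the hematopoietic compartment surface as somatic calls.

Raw reverse calls are noisy. `clonehema` provides the downstream analysis
as composable, tibble-in/tibble-out R functions:

* **Filter cascade** (`run_cascade()`): caller PASS + ≥2 supporting reads +
  VAF < 0.5, low-mappability masks, merging of adjacent SNVs into
  double-base substitutions, panel-of-normals / gnomAD frequency filters
  (strict "greater than" cutoffs 0.002 / 0.008 / 0.0003, or the frequency
  of a known driver hotspot), common-SNP exclusion, segmental-duplication
  and repeat masks, and exclusion of samples above the 97.5th percentile
  of mutation burden. Second-caller and mosaic-classifier call sets cut
  the *mutect* and *mosaic* catalogs from the *full* catalog by
  intersection.
* **Mutational signatures** (`build_catalog()`, `extract_signatures()`,
  `fit_exposures()`): SBS96 catalogs in the pyrimidine-centric channel
  order; de novo extraction by bootstrapped NMF with multiplicative
  updates minimizing generalized Kullback–Leibler divergence
  D(V ‖ WH) = Σ v log(v/ŵh) − v + ŵh; consensus signatures from
  cosine-greedy clustering of bootstrap solutions with silhouette-based
  rank selection; per-sample exposures by non-negative least squares;
  cosine matching against reference catalogs.
* **CH classification** (`classify_cohort()`): donors with a nonsilent
  mutation in a CH driver compendium gene are cases (tiered by how the
  gene was identified); the median *rate of hematopoiesis mutations per
  year of age* (HSC-signature exposure / age) across those donors then
  flags additional driverless cases whose rate is strictly greater.
* **Associations** (`fit_ch_model()`, `gene_treatment_associations()`,
  `age_exposure_trend()`): multivariable logistic regression of CH status
  on age, sex and treatment; per-gene treatment models with
  Benjamini–Hochberg FDR; the age–exposure Pearson trend.
* **Non-coding scanning** (`score_pvalue_table()`, `scan_variant()`,
  `classify_binding_change()`): exact PWM score-to-p-value tables by
  dynamic programming, ±15 bp reference/alternate haplotype scans, and
  the disruption/creation verdict at binding significance p < 1e-4.
* **Synthetic cohorts** (`simulate_cohort()`, `write_cohort()`): the real
  cohorts behind this kind of analysis are protected; the generator
  produces paired blood/tumor call sets with the statistical structure
  the analysis assumes (age-dependent HSC mutation accumulation, driver +
  hitchhiking passengers at clone-determined VAF, germline leakage shared
  with the tumor, artifact signatures), with ground truth stored apart
  from the emitted VCFs.

The packaged HSC reference profile (`hsc_reference_profile()`) is
**synthetic** — a clock-like stand-in generated in code, since the
healthy-donor genomes behind the real signature are access-controlled.

## Worked example

```r
library(clonehema)

cfg <- cohort_config(n_donors = 100, ch_prevalence = 0.5,
                     clone_fraction_range = c(0.3, 0.6),
                     germline_leak_rate = 5, mean_depth = 60, seed = 17)
cohort <- simulate_cohort(cfg)
cohort
#> <ch_cohort> 100 donors, 7024 blood calls, 496 tumor calls
#>   CH truth: 49/100 donors

res <- run_cascade(cohort$calls,
                   resources = germline_frequency_resource(cfg, "gnomAD"))
tidy(res)
#> # A tibble: 7 x 4
#>   step            variants_in variants_out removed
#>   <chr>                 <int>        <int>   <int>
#> 1 basic                  7024         6436     588
#> 2 low_mappability        6436         6436       0
#> 3 dbs_merge              6436         6436       0
#> 4 pon_gnomad             6436         6205     231
#> 5 common_snp             6205         6205       0
#> 6 region_masks           6205         6205       0
#> 7 hypermutator           6205         5824     381
```

The basic filter drops low-support calls (germline leakage sampled at
VAF ≥ 0.5, artifact variants with a single supporting read); the
frequency filter removes the leaked common polymorphisms; the
hypermutator rule excludes the highest-burden samples. Exposures and
classification then follow:

```r
ex <- fit_exposures(catalog_matrix(build_catalog(res$full)),
                    as_signature_matrix(hsc_reference_profile()))
cls <- classify_cohort(
  cohort$donors, res$full,
  tibble::tibble(gene = c("DNMT3A", "JAK2", "TET2"), tier = "known_CH"),
  tibble::tibble(sample_id = ex$sample_id, hsc_exposure = ex$prob))
ch_tier_counts(cls)
#> # A tibble: 5 x 3
#>   basis                           n cumulative
#>   <chr>                       <int>      <int>
#> 1 known_gene_germline_calling     0          0
#> 2 known_gene_reverse_calling     20         20
#> 3 discovered_gene                 0         20
#> 4 targeted_gene                   0         20
#> 5 rate_threshold                 11         31
```

`hsc_exposure` is the number of mutations NNLS attributes to the HSC
signature; `classify_cohort()` reports, per donor, whether they are a CH
case and on what basis (driver gene tier or the strict-median rate rule).

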