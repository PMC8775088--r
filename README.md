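# batchfst

Detection and quantification of sequencing-center **batch effects** in
multi-center genotype cohorts, focused on statistics that count **rare
events**: predicted loss-of-function (LoF) alleles, singletons, derived
singletons and archaic introgressed alleles per individual.

Sequencing errors are rare events themselves (0.1–1% of sequenced
nucleotides), so center-specific error processes bias exactly these
statistics. When samples are distributed unevenly across centers — as they
are in every large multi-center project — that technical signal masquerades
as population differentiation. `batchfst` is for population and medical
geneticists who need to know whether the rare-variant signal in a cohort
follows the biology or the sequencing facility.

## What it computes

**Rare-event counters** (strict inclusion rules): a variant is LoF iff all
three functional predictors call it deleterious *and* no individual carries
it in homozygosis; benign iff all three agree on benign; a singleton has
`AC = 1` over the whole cohort; a derived singleton additionally has
`REF == AA` with the degenerate ancestral codes `"."`, `"-"`, `"N"`
excluded; introgressed-allele counts sum the copies of the introgressed
allele at sites marked for the sample's own population.

**The core statistic** — per-SNV between-center Weir–Cockerham Fst under an
equal-n design (n = 5 per center by default), scaled by the maximum Fst
attainable at the site's minor allele frequency:

    theta_hat = a / (a + b + c)                  (variance components)
    MAF       = min(p, 1 - p),  p = sum_c a_c / (K * 2n)
    Fst_scaled = max(theta_hat, 0) / theta_max(MAF),  clamped to [0, 1]

where `theta_max(MAF)` is the estimator evaluated on the maximally
differentiated genotype configuration at that MAF (minor copies packed into
as few centers as possible, spread over heterozygotes — verified optimal by
exhaustive enumeration at small designs).

**Monte Carlo null and slope**: center labels are permuted within the
equal-n pool; per-MAF-category means of scaled Fst under permutation form
the null profile, and the OLS slope of observed on null category means
quantifies the batch effect (1 = exchangeable; > 1 = excess
differentiation concentrated at rare MAF). Categories that are pinned to
the identity by construction (zero variance across permutations) are
excluded from the fit.

**Association models**: hierarchical mixed models
`log(S) ~ center + (1 | continent/pop)` with a likelihood-ratio test for
the center term, correspondence analysis (with Pearson chi-square) of the
population-by-center sampling design, and pairwise Wilcoxon contrasts
within populations.

**Synthetic cohorts**: a seeded generator (neutral-like SFS rich in
singletons, Hardy–Weinberg genotypes, uneven center assignment,
center-specific site-recurrent genotype errors, predictor-label and
ancestral-allele structure, Sprime-style introgression tables) provides
every input the pipeline needs, with full truth bookkeeping — no downloads.

## A worked example

```r
library(batchfst)

spec <- cohort_spec(
  n_populations = 1, n_continents = 1, samples_per_pop = 200,
  n_variants = 20000,
  center_error_rates = c(BCM = 0.01, BGI = 0, BI = 0, WUGSC = 0),
  seed = 42)
co <- generate_cohort(spec)
sc <- fst_scan(co$genotypes, co$metadata, "POP01", n = 5, seed = 42)
fst_null(sc, co$genotypes, n_permutations = 100, seed = 43)
```

```
Monte Carlo null for scaled-Fst profile (100 permutations, 20 MAF categories)
  observed vs null slope = 1.287 (se 0.052, p = 8.17e-15), intercept = -0.0079
  fitted on 19 informative categories (1 pinned/degenerate excluded)
```

The slope of 1.29 says the observed between-center differentiation exceeds
the exchangeable-labels expectation — the injected 1% error rate at one
center is detected. With all error rates at zero the slope sits near 1.
The MAF profile of the same scan shows the effect is concentrated at rare
alleles:

```r
summarize_by_maf(sc)   # rho = -0.779 (p = 5.2e-05)
```

Counting rules on the bundled 10-variant toy fixture (every rule exercised:
consensus LoF with hom-alt exclusion, AA degenerate codes, derived calls,
population-specific introgression):

```r
gm <- read_vcf(system.file("extdata", "toy_cohort.vcf", package = "batchfst"))
md <- read_metadata(system.file("extdata", "toy_metadata.tsv", package = "batchfst"))
sp <- read_sprime_table(system.file("extdata", "toy_sprime.tsv", package = "batchfst"), gm)
rare_event_counts(gm, md, sp)
```

```
  sample  pop super_pop center n_lof n_benign n_singletons n_derived_singletons n_introgressed
1     S1 POPA       EUR   CTRX     1        1            1                    1              2
2     S2 POPA       EUR   CTRX     0        0            1                    0              2
3     S3 POPA       EUR   CTRY     0        0            1                    0              2
4     S4 POPB       EUR   CTRX     1        0            1                    0              0
5     S5 POPB       EUR   CTRY     0        1            1                    0              1
6     S6 POPB       EUR   CTRY     0        1            1                    0              2
```

End-to-end runs (simulate → count → CA → models → Fst → null → report) are
driven by `run_config()` / `run_pipeline()`, write plain-text artifacts plus
a digest manifest, and are byte-identical under a fixed seed. See the
methods vignette (`vignettes/batch-effect-methods.Rmd`) for the statistical
details and design choices.

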