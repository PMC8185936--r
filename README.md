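# mitomr

Mitochondrial genome copy number (MT-CN) measured by bulk DNA sequencing of
blood is heritable and associated with metabolic traits — but a bulk
measurement mixes per-cell mitochondrial abundance with the cell-type
composition of blood. `mitomr` implements, for statistical geneticists and
epidemiologists working with individual-level cohort data, the full
computational chain needed to study that question:

* **MT-CN estimation** from sequencing coverage,
  `MT-CN = 2 × (mt depth) / (haploid autosomal coverage)`, with the mean
  mitochondrial depth for whole-genome data (`mtcn_wgs()`) and the maximum
  depth for peaked hybrid-capture exome coverage (`mtcn_wes()`), followed by
  batch-wise age/age²/sex residualization and double rank-based inverse
  normal transformation (`normalize_mtcn()`).
* **Penalized-instrument Mendelian randomization** of X = ln(MT-CN) on
  Y = ln(insulin) (`run_mr()`): covariate sets A (outcome-associated) and B
  (exposure-associated given A) adjusted without penalty while an L1- or
  L2-penalized regression of X on the genotype matrix G builds an
  instrument Z with out-of-fold weights β_G^(−j) over K = 5 folds; the
  causality regression of Y on Z adjusts every covariate with a first-order
  association with Z or Y; missing phenotypes are multiply imputed by
  chained regression trees, estimates pooled by Rubin's rules
  (t test, df = m − 2), and datasets combined by inverse-variance-weighted
  meta-analysis (Z test).
* **Polygenic-score replication** (`compute_prs()`, `prs_association()`):
  the averaged weights β̄_G projected onto hard-called dosages
  (DS = P(0/1) + 2P(1/1), thresholds 0.5/1.5) of an independent cohort,
  tested against cell counts and metabolic traits with and without
  neutrophil/platelet adjustment — the cell-count mediation comparison.
* **Phenome-wide screen** (`curate_phenotypes()`, `run_screen()`) with dual
  raw/inverse-normal handling of continuous traits and
  Benjamini–Hochberg + Storey FDR control (`qvalues_bh_storey()`).
* **A synthetic cohort generator** (`simulate_cohort()`,
  `simulate_coverage()`) reproducing the assumed causal structure —
  polygenic exposure, latent confounding, a cell-composition factor shared
  with neutrophil/platelet counts, batch shifts, missing-at-random
  phenotypes, Poisson per-base sequencing depth — so every stage is
  testable without access-controlled data.

The methods vignette (`vignettes/mitomr-methods.Rmd`) documents the model,
its assumptions, every tunable default, and the design decisions.

## Worked example

Simulate a cohort, estimate and normalize MT-CN from simulated coverage,
and run the MR causality test with both penalties:

```r
library(mitomr)
co  <- simulate_cohort(cohort_config(n_samples = 1500, n_variants = 60, seed = 7))
cov <- simulate_coverage(co, mode = "wgs", seed = 8)
raw <- mtcn_wgs(cov$summary)
rec <- data.frame(sample_id = co$sample_id, raw_mtcn = raw,
                  batch = co$batch, age = co$age, sex = co$sex)
norm <- normalize_mtcn(rec)
cor(norm$normalized_mtcn, co$X, method = "spearman")
#> spearman(normalized, true ln MT-CN): 0.988

fit <- run_mr(list(cohort = co), penalty = "both", m_imputations = 10,
              maxit = 3, seed = 9)
print(fit)
#> Penalized-instrument Mendelian randomization (MT-CN -> insulin)
#>   1 dataset(s), 10 imputations, 5 folds, penalty: both
#>   L1 meta (IVW): beta = 0.1979, se = 0.2132, z = 0.93, p = 0.353
#>   L2 meta (IVW): beta = 0.0764, se = 0.1676, z = 0.46, p = 0.649
```

The printed `beta` is the pooled coefficient of the genetic instrument in
the causality regression of log insulin on Z — an estimate of the causal
effect of log MT-CN on log insulin when the instrument is calibrated. Here
the cohort was simulated with a true effect of 0.15; at n = 1500 both
penalties give estimates consistent with it (and with zero — a cohort this
small is underpowered, which is why the pipeline meta-analyzes datasets).
`summary(fit)` tabulates per-dataset pooled rows and the meta row;
`posthoc_outlier_rerun(fit, list(cohort = co))` repeats the analysis after
excluding high-leverage, high-residual samples.

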