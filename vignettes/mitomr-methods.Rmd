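---
title: "Methods: mitochondrial copy number, penalized-instrument Mendelian randomization, and cell-count mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial copy number, penalized-instrument Mendelian randomization, and cell-count mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomr)
```

## The scientific problem

Mitochondrial genome copy number (MT-CN) measured by bulk DNA sequencing of
whole blood varies across people and is associated with metabolic traits,
most strongly fasting insulin. Because blood is a mixture of cell types with
very different mitochondrial content (platelets carry mitochondria but no
nucleus), a bulk MT-CN measurement confounds per-cell mitochondrial
abundance with cell-type composition. This package implements the
computational chain needed to study that question on individual-level data:

1. estimate raw MT-CN from sequencing coverage,
2. normalize it into an analysis phenotype,
3. test whether MT-CN is causally related to insulin with a
   penalized-regression Mendelian randomization (MR) design built for the
   situation where no robust genotype-exposure associations are known in
   advance,
4. project the resulting instrument weights as a polygenic score (PRS) onto
   an independent cohort and ask whether its trait associations survive
   adjustment for neutrophil and platelet counts (the cell-count mediation
   question), and
5. screen the score against an arbitrary phenotype table with false
   discovery control.

Every stage is exercisable on a synthetic cohort generator
(`simulate_cohort()`) that reproduces the statistical structure the analysis
assumes, so the pipeline is testable without access-controlled cohort data.

## MT-CN estimation

Raw MT-CN is twice the ratio of mitochondrial read depth to haploid
autosomal coverage:

* `mtcn_wgs()`: `2 * mean mt depth / haploid autosomal coverage`. Suitable
  for whole-genome data where coverage along the mitochondrial contig is
  approximately uniform; a diploid-equivalent contig gives the value 2.
* `mtcn_wes()`: `2 * max mt depth / haploid autosomal coverage`. With
  hybrid-capture exome data the mitochondrial coverage profile is sharply
  peaked around probe sites, so the mean depth dilutes the signal with
  off-target troughs; the maximum tracks copy number through the probe
  peaks. Which estimator has the higher validity on real capture data is an
  empirical question (it depends on the probe chemistry), so
  `estimator_concordance()` reports the squared correlation between paired
  estimates rather than asserting a winner.

Both estimators are scale-equivariant: doubling all depths together with the
autosomal coverage leaves the estimate unchanged.

Depth input follows the samtools-depth dialect: TSV of (contig, 1-based
position, depth), with absent positions read as depth zero
(`read_depth_table()`), since per-base depth emitters omit zero-coverage
bases.

### Normalization

`normalize_mtcn()` turns raw estimates into the analysis phenotype: within
each acquisition batch, raw values are residualized by OLS on age, age² and
sex, the residuals are inverse rank normal transformed, the batches are
pooled, and the pooled values are transformed once more. Two details:

* sex is included per batch only when the batch contains both sexes —
  single-sex batches (such as an all-male cohort) would otherwise produce a
  rank-deficient design;
* the inverse rank normal transform (`inverse_rank_normal()`) maps
  tie-averaged ranks through `qnorm((r - 0.5)/n)`. The half offset makes
  the output exactly mean-zero and symmetric for tie-free input; average
  ranks make it deterministic under ties.

Because each batch is reduced to ranks before pooling, the output is
exactly invariant to increasing batch-constant affine distortions of the raw
values — in particular to additive batch mean shifts, which is the batch
artifact the procedure exists to remove. It is *not* invariant to arbitrary
nonlinear monotone distortions once covariate residualization is involved,
since residual ranks are not preserved by nonlinear maps of the response.

## The Mendelian randomization design

The causal diagram: genotypes G → instrument Z → exposure X = ln(raw MT-CN)
→ outcome Y = ln(fasting insulin), with a latent confounder U of the X–Y
relation. A significant Z–Y association supports X being causal for Y,
provided Z affects Y only through X and is unconfounded. With no established
genotype–exposure loci to draw on, the instrument is built from many common
variants at once by penalized regression, and the MR assumptions are pushed
toward validity by two covariate-screening devices:

* **Sets A and B** (`partition_covariates()`): A = covariates marginally
  associated with Y; B = remaining covariates associated with X conditional
  on A. Both are adjusted *without penalty* in the instrument-building
  regression of X on G, so that Z is constructed to be orthogonal to the
  measured confounder candidates. A takes precedence: a covariate
  associated with both lands in A.
* **Sets I–IV** (`classify_for_causality()`): after Z is built, each
  covariate is tested marginally against Z and against Y; everything with a
  first-order association with either (sets II, III, IV) is adjusted in the
  causality regression, set I is left out. This two-by-two reading of the
  first-order-association diagram is an interpretation — the screening
  threshold and exact membership rules are design choices here, defaulting
  to a Bonferroni threshold `0.05 / ncol(W)` to keep false covariate
  inclusion rare.

### Out-of-fold instruments

`build_instrument()` splits samples into K = 5 folds. For fold j, weights
β⁽⁻ʲ⁾ are fit on the other folds and applied only to fold j's genotype rows,
so each sample's Z never uses weights that saw its own exposure. This
matters: in-sample prediction leaks exposure noise into Z, which correlates
Z with the non-genetic part of X and biases the causality test (the test
suite demonstrates the contamination difference directly). The averaged
weights across folds, β̄_G, are what later becomes the PRS.

### Penalized fits

`fit_penalized()` minimizes `½‖y − Pβ − Fγ‖² + λ·pen(β)` with
pen = ‖β‖₁ (lasso) or ½‖β‖₂² (ridge); the free block F (intercept plus
sets A and B) is never penalized. The free block is profiled out exactly by
the Frisch–Waugh step, the lasso is solved by cyclic coordinate descent on
the Gram matrix (convergence when the largest coefficient change is below
1e-7, at most 1e5 sweeps), and the ridge by a closed-form solve. Penalized
columns are standardized to unit variance internally so λ is comparable
across variants, with coefficients reported on the original scale;
`standardize = FALSE` solves the stated objective on the columns as given
(this is the setting under which the orthonormal-design ridge identity
β = Pᵀy/(1+λ) is exact). λ is either fixed or chosen per training fold by
inner 5-fold cross-validation over a log-spaced grid anchored at
max|Pᵀy| with the one-standard-error rule — deterministic given the seed.
Whether the original analysis shared λ across folds is unknown; refitting
per fold is the choice here because it keeps each fold's weights a function
of its own training data only.

### Missing data, pooling, meta-analysis

Phenotype missingness is handled by chained-equations multiple imputation
(`mi_impute()`): each incomplete variable is modelled on all others with a
regression tree (maximum depth 5, minimum terminal node 10 — tree
hyperparameters are not dictated by anything and these are conventional
values), and imputed values are drawn from the observed donors in the
matched terminal node, so imputations are always observed values of the
variable. Variables with few observed rows fall back to Bayesian linear
regression with a posterior noise draw. Each of the m imputed tables is
carried through the *entire* procedure — covariate partition, instrument,
classification, causality test — and the m estimates are pooled by Rubin's
rules (`rubin_combine()`): total variance = mean within-imputation variance
plus (1 + 1/m) times the between-imputation variance. The pooled statistic
is referred to a t distribution with **m − 2** degrees of freedom. That df
convention (998 at m = 1000) is adopted as the pipeline's convention; a
Barnard–Rubin adjusted df is available via `df_method = "barnard-rubin"`
since the classical large-sample df is another defensible reading.

Datasets (for example a sequenced subset and an array-imputed subset of the
same study) are analyzed separately and combined by fixed-effect
inverse-variance weighted meta-analysis with a Z test
(`meta_fixed_ivw()`); a DerSimonian–Laird random-effects variant
(`meta_random_dl()`) is provided for heterogeneous settings.

### Outlier handling

Two stages, matching the pipeline's design: before analysis, multivariate
trait outliers are removed by iterated PCA exclusion
(`pca_outlier_iterate()`, up to 3 rounds at 6 component SDs) plus a
Mahalanobis-distance cut; after a run, `posthoc_outlier_rerun()` records,
within every imputation, the top 10 samples by leverage among those with
standardized residual above 1 in the causality regression, excludes the
union, and re-runs the procedure, reporting both results side by side. The
residual/leverage cutoffs in `nullmodel_outliers()` (6 SD, leverage 3p/n
with 2 SD residuals) are declared defaults motivated by normal theory, not
reproductions of any published thresholds.

## PRS replication and cell-count mediation

`compute_prs()` projects β̄_G onto an independent cohort's hard-called
genotypes: expected dosage DS = P(0/1) + 2·P(1/1) (`expected_dosage()`),
hard calls at 0.5 and 1.5 with boundaries assigned upward (`hard_call()`),
score = G̃·β̄_G. Traits are prepared (`prepare_traits()`) by reconstructing
lymphocyte counts as leukocyte count × lymphocyte fraction (percent scales
auto-detected), log-transforming, and standardizing cell counts by sex.
Associations use the design
`trait ~ PRS + Age + Age² + Sex + Age:Sex + Age²:Sex + PCs`
(`prs_association()`), optionally adding neutrophil and platelet counts.
The mediation logic: if the score's trait associations are carried by
cell-type composition, adjusting for neutrophil/platelet counts should
attenuate them; if composition is irrelevant, adjustment should change
nothing systematically. Both behaviours are reproduced on synthetic cohorts
in the test suite.

## Phenome screen

`curate_phenotypes()` implements the three curation rules this pipeline
relies on: continuous variables are emitted both raw and inverse rank
normalized; unordered categorical variables are expanded to one-vs-rest
indicators and tested by logistic regression directly (the level coding is
a design choice here); sex-specific categorical traits and constant columns
are excluded with a recorded reason. `run_screen()` tests every curated
form against the score with the standard covariate design and controls FDR
with `qvalues_bh_storey()` over two families: categorical + normalized
continuous (primary, the conservative and outlier-robust reading) and
categorical + raw continuous (secondary). π₀ is estimated by the smoother
method: `mean(p > λ)/(1 − λ)` on the grid λ = 0.05, …, 0.95, cubic
smoothing spline evaluated at the largest λ, clipped to (0, 1]; fixing
π₀ = 1 reduces the procedure exactly to Benjamini–Hochberg.

## The synthetic cohort generator

`simulate_cohort()` draws, per `cohort_config()`:

* genotypes: independent variants, MAF uniform on (0.05, 0.5), hard calls
  Binomial(2, MAF), genotype-probability triplets jittered around the hard
  call by a flat-Dirichlet mixture (weight `gp_noise = 0.1`) and dosages
  recomputed from them. Variants are simulated independently — the MR
  method does not require linkage disequilibrium to be exercised, and no
  attempt is made to mimic human LD structure;
* a standardized polygenic score with per-variant effects
  N(0, h²/m), `h2_instrument = 0.2` of exposure variance by default;
* a cell-type composition factor C correlated with the polygenic score
  (`composition_loading = 0.3`) and loading on log MT-CN
  (`composition_effect = 0.3`) and on neutrophil/platelet counts; how much
  of real MT-CN variance is compositional versus intracellular is not a
  quantity anyone has pinned down, so this loading is a free emulation
  parameter, not an estimate. An optional direct composition → outcome path
  (`composition_outcome_effect`, default 0) produces the regime where cell
  counts drive the outcome and cell-count adjustment attenuates score-trait
  associations; it is off by default so that the causal-recovery settings
  satisfy the exclusion restriction;
* a latent standard-normal confounder with loadings 0.3 on both exposure
  and outcome; three covariate groups (3 outcome-linked, 3 exposure-linked,
  4 null, loadings 0.15); age and sex effects; exposure noise set by
  difference so the variance components add to one;
* the outcome Y = θ·X + covariates + confounder + noise with θ = 0.15 by
  default on the log-insulin scale;
* log MT-CN located at log(200) with scale 0.4 (a typical blood MT-CN
  level around 200 copies with ~40% coefficient of variation), additive
  batch mean shifts (0, +15, −10 copies) on the raw scale across three
  acquisition batches, the first batch all-male;
* missing-at-random phenotype masking at marginal rate 0.05, driven by
  observed age and sex only — which is exactly the mechanism
  chained-equations imputation can recover from;
* sequencing depth per base Poisson with rate
  (MT-CN/2) × haploid coverage × profile, uniform profile for WGS and a
  raised-cosine probe-peak train for WES (`wes_profile_peakedness = 0.8`,
  zero peakedness reduces to uniform), haploid coverage 20× with 5%
  lognormal jitter.

What the generator does *not* emulate: linkage disequilibrium and
population structure, relatedness, sequence-level read artifacts (NUMT
misalignment, GC bias), informative missingness, and real phenotype
distributions. Passing tests therefore demonstrate that the procedures are
correct under their stated assumptions, not that those assumptions hold in
any particular cohort.

## Validation problem sizes

The test suite validates the pipeline at deliberately scaled problem sizes:
causal-effect recovery at n = 4000, 100 variants, θ = 0.15, 20 imputations
(both penalties, cross-validated λ); null calibration of the pooled test
over 200 replicates at n = 2000, 50 variants, 10 imputations with fixed
ridge shrinkage and a single chained-equation sweep per imputation (the
chains are short because only ~5% of a dozen variables are missing);
estimator recovery over 100 simulated genomes; mediation at n = 6000 with
composition loading 0.5 and outcome loading 0.15 against a zero-loading
control; and all-null FDR behaviour of the screen over 100 replicates of
200 traits at n = 2000. Closed-form oracles (ridge identity, Rubin/IVW/DL
arithmetic, BH reduction, Mahalanobis and hat-matrix identities) are checked
exactly.

## Known limitations

* The causality estimate from the Y-on-Z regression is an instrument-scale
  association; it coincides with the causal effect of X only to the extent
  that Z is a calibrated predictor of X (cross-validated shrinkage is what
  pushes it toward calibration). Weak-instrument diagnostics beyond
  corr(Z, X) are out of scope.
* Two-sample summary-statistic MR estimators (IVW-Egger and relatives) are
  not implemented; the design here is individual-level by construction.
* The covariate screening can neither discover unmeasured confounders nor
  guard against collider bias from adjusting a variable caused by both Z
  and Y; these are properties of the design being implemented, discussed at
  length in its source literature.
* Mixed-model association, kernel rare-variant tests and REML heritability
  belong to external tooling and are deliberately absent.
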