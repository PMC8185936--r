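# Synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes: a polygenic effect on log mitochondrial copy
# number, a latent confounder linking exposure and outcome, covariate blocks
# that are outcome-associated / exposure-associated / null, a cell-type
# composition factor shared with the blood counts, acquisition batches with
# mean shifts on the raw copy-number scale, age/sex effects, missing-at-random
# phenotypes, and Poisson sequencing depth on the mitochondrial contig.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a mid-sized population cohort: common variants
#' (MAF 5-50%) explaining `h2_instrument` of the variance of log MT-CN, a
#' causal effect `theta` of log MT-CN on log insulin, moderate latent
#' confounding, three acquisition batches (the first all-male), and a
#' cell-type composition factor that couples true MT-CN to neutrophil and
#' platelet counts with loading `composition_loading`.
#'
#' @param n_samples,n_variants cohort and genotype panel size.
#' @param maf_range minor allele frequency range in (0, 0.5].
#' @param theta causal effect of log MT-CN on log insulin.
#' @param h2_instrument variance fraction of log MT-CN explained by genotypes.
#' @param confounder_strengths `c(delta_X, delta_Y)` loadings of the latent
#'   confounder on exposure and outcome.
#' @param n_covariates counts per covariate group
#'   `c(outcome_linked, exposure_linked, null)`.
#' @param covariate_effect per-covariate loading for the linked groups.
#' @param batch_offsets additive mean shifts per batch on the raw MT-CN scale.
#' @param missing_rate marginal phenotype missingness (missing at random,
#'   driven by observed age and sex only).
#' @param composition_loading correlation of the composition factor with the
#'   standardized polygenic score (genetics -> cell composition).
#' @param composition_effect loading of the composition factor on log MT-CN.
#' @param composition_outcome_effect direct loading of the composition factor
#'   on the outcome (default 0: all composition influence on Y flows through
#'   log MT-CN; a positive value emulates cell counts driving the outcome
#'   directly, the regime where cell-count adjustment attenuates score-trait
#'   associations).
#' @param gp_noise genotype-probability jitter in \[0, 1); 0 gives exact
#'   hard-call triplets.
#' @param age_effects `c(age, age^2, sex)` loadings on standardized log MT-CN.
#' @param depth_params list: haploid_autosomal_coverage, mtcn_location,
#'   mtcn_scale (log-scale location/scale of true MT-CN), mt_genome_length,
#'   wes_profile_peakedness.
#' @param seed integer seed; all generation is reproducible from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 2000, n_variants = 100,
                          maf_range = c(0.05, 0.5),
                          theta = 0.15, h2_instrument = 0.2,
                          confounder_strengths = c(0.3, 0.3),
                          n_covariates = c(outcome_linked = 3,
                                           exposure_linked = 3, null = 4),
                          covariate_effect = 0.15,
                          batch_offsets = c(0, 15, -10),
                          missing_rate = 0.05,
                          composition_loading = 0.3,
                          composition_effect = 0.3,
                          composition_outcome_effect = 0,
                          gp_noise = 0.1,
                          age_effects = c(-0.10, 0.02, -0.05),
                          depth_params = list(
                            haploid_autosomal_coverage = 20,
                            mtcn_location = log(200),
                            mtcn_scale = 0.4,
                            mt_genome_length = 16569,
                            wes_profile_peakedness = 0.8),
                          seed = 1L) {
  if (n_samples < 2) stop("n_samples must be at least 2")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (h2_instrument < 0 || h2_instrument >= 1)
    stop("h2_instrument must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (gp_noise < 0 || gp_noise >= 1) stop("gp_noise must lie in [0, 1)")
  if (composition_loading < 0 || composition_loading >= 1)
    stop("composition_loading must lie in [0, 1)")
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate genotype dosages and genotype-probability triplets
#'
#' Per-variant MAF is uniform on `maf_range`; hard genotypes are
#' Binomial(2, MAF); probability triplets are a mixture of the hard-call
#' one-hot vector and a flat Dirichlet draw with weight `gp_noise`, so each
#' triplet sums to one and the dosage is recomputed as
#' `P(0/1) + 2 P(1/1)`.
#'
#' @param n,m samples and variants.
#' @param maf_range MAF range in (0, 0.5].
#' @param gp_noise jitter weight in \[0, 1).
#' @param seed integer seed.
#' @return list(dosages n x m, gp n x m x 3, maf length m).
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               gp_noise = 0.1, seed = 1L) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  set.seed(seed)
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  hard <- vapply(maf, function(f) stats::rbinom(n, 2L, f), integer(n))
  gp <- array(0, dim = c(n, m, 3))
  for (g in 0:2) gp[, , g + 1][hard == g] <- 1
  if (gp_noise > 0) {
    # flat Dirichlet(1,1,1) via normalized exponentials
    e <- array(stats::rexp(n * m * 3), dim = c(n, m, 3))
    e <- e / as.vector(e[, , 1] + e[, , 2] + e[, , 3])
    gp <- (1 - gp_noise) * gp + gp_noise * e
  }
  dos <- gp[, , 2] + 2 * gp[, , 3]
  sample_ids <- sprintf("s%05d", seq_len(n))
  variant_ids <- sprintf("v%04d", seq_len(m))
  dimnames(dos) <- list(sample_ids, variant_ids)
  dimnames(gp) <- list(sample_ids, variant_ids, c("AA", "AB", "BB"))
  list(dosages = dos, gp = gp, maf = maf)
}

#' Simulate a full synthetic cohort
#'
#' Draws the structural model: standardized polygenic score `S`; composition
#' factor `C = a S + sqrt(1 - a^2) eta`; latent confounder `U ~ N(0,1)`;
#' standardized exposure component built from the genetic, composition,
#' exposure-linked covariate, confounder, age/sex and noise pieces with the
#' noise variance set by difference so the components match the config; log
#' MT-CN `X = mtcn_location + mtcn_scale * X_std`; outcome
#' `Y = theta X + gamma_A W_A + delta_Y U + eps_Y` (log insulin scale). Raw
#' MT-CN receives additive batch mean shifts, and phenotype missingness is
#' missing-at-random through observed age and sex.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` list: dosages, gp, W, U, X, Y, age, sex,
#'   batch, cell_counts, mtcn_raw, missing_mask, truth, config.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  n <- config$n_samples; m <- config$n_variants
  geno <- simulate_genotypes(n, m, config$maf_range, config$gp_noise,
                             seed = config$seed)
  set.seed(config$seed + 1L)

  h2 <- config$h2_instrument
  a_comp <- config$composition_loading
  b_comp <- config$composition_effect
  g_direct <- sqrt(h2) - b_comp * a_comp
  if (g_direct < 0)
    stop("composition_loading * composition_effect exceeds sqrt(h2_instrument)")

  Gs <- scale(geno$dosages)
  beta_g <- stats::rnorm(m, 0, sqrt(ifelse(h2 > 0, h2 / m, 1e-12)))
  S <- as.numeric(Gs %*% beta_g)
  S_h <- if (stats::sd(S) > 0) S / stats::sd(S) else S
  C <- a_comp * S_h + sqrt(1 - a_comp^2) * stats::rnorm(n)
  U <- stats::rnorm(n)

  batch <- sample.int(3L, n, replace = TRUE, prob = c(0.5, 0.25, 0.25))
  sex <- ifelse(batch == 1L, 1L, stats::rbinom(n, 1L, 0.5))  # batch 1 all-male
  age <- round(stats::runif(n, 25, 75))
  age_s <- as.numeric(scale(age))

  nW <- config$n_covariates
  W <- matrix(stats::rnorm(n * sum(nW)), n, sum(nW))
  colnames(W) <- c(sprintf("w_out%d", seq_len(nW[1])),
                   sprintf("w_exp%d", seq_len(nW[2])),
                   sprintf("w_null%d", seq_len(nW[3])))
  idx_A <- seq_len(nW[1])
  idx_B <- nW[1] + seq_len(nW[2])
  gam <- config$covariate_effect
  dX <- config$confounder_strengths[1]
  dY <- config$confounder_strengths[2]
  ae <- config$age_effects

  var_used <- h2 + b_comp^2 * (1 - a_comp^2) + nW[2] * gam^2 + dX^2 +
    ae[1]^2 + ae[2]^2 * 2 + ae[3]^2 * 0.25
  if (var_used >= 1)
    stop("exposure variance components exceed 1; reduce loadings")
  X_std <- g_direct * S_h + b_comp * C +
    as.numeric(W[, idx_B, drop = FALSE] %*% rep(gam, nW[2])) +
    dX * U + ae[1] * age_s + ae[2] * (age_s^2 - 1) + ae[3] * sex +
    stats::rnorm(n, 0, sqrt(1 - var_used))

  dp <- config$depth_params
  X <- dp$mtcn_location + dp$mtcn_scale * X_std   # ln(MT-CN)
  mtcn_true <- exp(X)
  mtcn_raw <- mtcn_true + config$batch_offsets[batch]

  c_y <- config$composition_outcome_effect
  var_y <- config$theta^2 * dp$mtcn_scale^2 + nW[1] * gam^2 + dY^2 + c_y^2
  if (var_y >= 1) stop("outcome variance components exceed 1; reduce loadings")
  Y <- config$theta * X + c_y * C +
    as.numeric(W[, idx_A, drop = FALSE] %*% rep(gam, nW[1])) +
    dY * U + stats::rnorm(n, 0, sqrt(1 - var_y))

  # blood counts (10^9 cells/L; platelets in 10^9/L) sharing the factor C
  neut <- exp(log(3.5) + 0.30 * (0.8 * C + 0.6 * stats::rnorm(n)))
  plat <- exp(log(250) + 0.20 * (0.6 * C + 0.8 * stats::rnorm(n)))
  lymph <- exp(log(1.9) + 0.30 * stats::rnorm(n))
  mono <- exp(log(0.5) + 0.30 * stats::rnorm(n))
  leuk <- neut + lymph + mono + 0.2
  cell_counts <- data.frame(
    leukocyte = leuk, neutrophil = neut,
    lymphocyte_pct = 100 * lymph / leuk,
    monocyte = mono, platelet = plat
  )

  pheno_names <- c("X", "Y", colnames(W))
  if (config$missing_rate > 0) {
    p_mis <- stats::plogis(stats::qlogis(config$missing_rate) +
                             0.4 * age_s + 0.2 * (sex - 0.5))
    missing_mask <- vapply(pheno_names, function(v)
      stats::runif(n) < p_mis, logical(n))
  } else {
    missing_mask <- matrix(FALSE, n, length(pheno_names))
  }
  missing_mask <- as.data.frame(missing_mask)
  names(missing_mask) <- pheno_names

  sample_ids <- rownames(geno$dosages)
  structure(list(
    sample_id = sample_ids,
    dosages = geno$dosages, gp = geno$gp, maf = geno$maf,
    W = W, U = U, C = C, X = X, Y = Y,
    age = age, sex = sex, batch = batch,
    cell_counts = cell_counts, mtcn_raw = mtcn_raw,
    missing_mask = missing_mask,
    truth = list(beta_g = beta_g, theta = config$theta,
                 h2_instrument = h2, g_direct = g_direct,
                 composition_loading = a_comp, composition_effect = b_comp,
                 confounder_strengths = c(dX, dY),
                 covariate_effect = gam, batch_offsets = config$batch_offsets,
                 mtcn_location = dp$mtcn_location,
                 mtcn_scale = dp$mtcn_scale),
    config = config
  ), class = "synthetic_cohort")
}

#' Observed phenotype table for a cohort
#'
#' Applies the missingness mask, returning the analysis-facing table with
#' `NA` where a value is unobserved.
#'
#' @param cohort a `synthetic_cohort`.
#' @return data.frame with columns X, Y and the covariates.
#' @export
cohort_phenotypes <- function(cohort) {
  tab <- data.frame(X = cohort$X, Y = cohort$Y, cohort$W,
                    check.names = FALSE)
  for (v in names(cohort$missing_mask)) tab[[v]][cohort$missing_mask[[v]]] <- NA
  rownames(tab) <- cohort$sample_id
  tab
}

# Raised-cosine peak-train capture profile along the mitochondrial contig,
# normalized to mean 1; peakedness 0 reduces to the uniform (WGS) profile.
wes_profile <- function(L, peakedness, n_peaks = 40) {
  if (peakedness == 0) return(rep(1, L))
  pos <- seq_len(L)
  raw <- (0.5 * (1 + cos(2 * pi * n_peaks * pos / L)))^4
  (1 - peakedness) + peakedness * raw / mean(raw)
}

#' Simulate per-base mitochondrial sequencing depth
#'
#' Per-base depth is Poisson with rate
#' `(MT-CN / 2) * haploid_autosomal_coverage * profile(b)`; the profile is
#' uniform in WGS mode and a raised-cosine probe-peak train in WES mode. The
#' per-sample haploid autosomal coverage is returned with small lognormal
#' jitter.
#'
#' @param mtcn either a `synthetic_cohort` (its batch-shifted raw MT-CN is
#'   used) or a numeric vector of true MT-CN values.
#' @param depth_params list as in [cohort_config()]; defaults to the cohort's
#'   own when a cohort is supplied.
#' @param mode `"wgs"` or `"wes"`.
#' @param seed integer seed.
#' @param return_profiles also return the L x n per-base depth matrix
#'   (memory-heavy; intended for small n).
#' @return list with `summary` (data.frame sample_id, mean_mt_depth,
#'   max_mt_depth, haploid_autosomal_coverage) and optionally `profiles`.
#' @export
simulate_coverage <- function(mtcn, depth_params = NULL,
                              mode = c("wgs", "wes"), seed = 1L,
                              return_profiles = FALSE) {
  mode <- match.arg(mode)
  if (inherits(mtcn, "synthetic_cohort")) {
    if (is.null(depth_params)) depth_params <- mtcn$config$depth_params
    ids <- mtcn$sample_id
    mtcn <- mtcn$mtcn_raw
  } else {
    ids <- sprintf("s%05d", seq_along(mtcn))
  }
  if (is.null(depth_params)) stop("depth_params required for a numeric mtcn")
  dp <- depth_params
  if (dp$haploid_autosomal_coverage <= 0 || any(mtcn <= 0))
    stop("coverage parameters must be positive")
  L <- dp$mt_genome_length
  prof <- if (mode == "wgs") rep(1, L) else
    wes_profile(L, dp$wes_profile_peakedness)
  set.seed(seed)
  n <- length(mtcn)
  hap <- dp$haploid_autosomal_coverage * exp(stats::rnorm(n, 0, 0.05))
  mean_d <- max_d <- numeric(n)
  profiles <- if (return_profiles) matrix(0L, L, n) else NULL
  for (i in seq_len(n)) {
    lam <- (mtcn[i] / 2) * hap[i] * prof
    d <- stats::rpois(L, lam)
    mean_d[i] <- mean(d)
    max_d[i] <- max(d)
    if (return_profiles) profiles[, i] <- d
  }
  out <- list(summary = data.frame(
    sample_id = ids, mean_mt_depth = mean_d, max_mt_depth = max_d,
    haploid_autosomal_coverage = hap
  ))
  if (return_profiles) out$profiles <- profiles
  out
}
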