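# Mendelian randomization machinery: covariate screening, instrument
# construction, multiple imputation, the causality test, and pooling.

test_that("covariate partition recovers planted associations", {
  set.seed(51)
  n <- 2000
  W <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("w", 1:6)))
  X <- 0.5 * W[, 2] + rnorm(n)
  Y <- 0.5 * W[, 1] + rnorm(n)
  part <- partition_covariates(W, X, Y, alpha_screen = 0.001)
  expect_identical(part$set_A, "w1")
  expect_identical(part$set_B, "w2")
  # all-null covariates: both sets empty at a strict threshold
  part0 <- partition_covariates(matrix(rnorm(n * 8), n, 8,
                                       dimnames = list(NULL, paste0("z", 1:8))),
                                rnorm(n), rnorm(n), alpha_screen = 0.001)
  expect_length(part0$set_A, 0)
  expect_length(part0$set_B, 0)
  # a covariate associated with both lands in A only (A takes precedence)
  Wb <- cbind(both = X + Y + rnorm(n), W)
  pb <- partition_covariates(Wb, X, Y, alpha_screen = 0.001)
  expect_true("both" %in% pb$set_A)
  expect_false("both" %in% pb$set_B)
  expect_error(partition_covariates(W[, 0], X, Y), "zero columns")
  expect_warning(partition_covariates(cbind(W, const = 1), X, Y), "constant")
})

test_that("causality-set classification partitions every covariate", {
  set.seed(52)
  n <- 2000
  Z <- rnorm(n)
  Y <- rnorm(n)
  W <- cbind(null1 = rnorm(n), null2 = rnorm(n),
             zy = 0.4 * Z + 0.4 * Y + rnorm(n),
             zonly = 0.4 * Z + rnorm(n), yonly = 0.4 * Y + rnorm(n))
  cls <- classify_for_causality(W, Z, Y, alpha_screen = 0.001)
  expect_setequal(c(cls$set_I, cls$set_II, cls$set_III, cls$set_IV),
                  colnames(W))
  expect_true(all(c("null1", "null2") %in% cls$set_I))
  expect_identical(cls$set_II, "zy")
  expect_identical(cls$set_III, "zonly")
  expect_identical(cls$set_IV, "yonly")
  expect_setequal(cls$adjusted, c("zy", "zonly", "yonly"))
  # all-null: everything in set I, nothing adjusted
  cls0 <- classify_for_causality(matrix(rnorm(n * 5), n, 5,
                                        dimnames = list(NULL, paste0("n", 1:5))),
                                 Z, Y, alpha_screen = 0.001)
  expect_length(cls0$adjusted, 0)
})

test_that("instrument construction honours the out-of-fold discipline", {
  co <- small_cohort(n = 400, m = 30, seed = 53)
  inst <- build_instrument(co$X, co$dosages, co$W[, 1:2],
                           penalty_spec("l2", 20), K = 5, seed = 54)
  # every sample in exactly one fold
  expect_equal(length(inst$fold_assignment), 400)
  expect_setequal(unique(inst$fold_assignment), 1:5)
  # Z for fold j is reproducible from (G_j, beta^(-j)) alone
  for (j in 1:5) {
    idx <- inst$fold_assignment == j
    expect_equal(inst$Z[idx],
                 as.numeric(co$dosages[idx, ] %*% inst$beta_G_per_fold[, j]))
  }
  expect_equal(inst$beta_G_bar, rowMeans(inst$beta_G_per_fold))
  # genotype-independent exposure + heavy shrinkage: Z identically zero
  set.seed(55)
  inst0 <- build_instrument(rnorm(400), co$dosages, NULL,
                            penalty_spec("l1", 1e6), K = 5, seed = 56)
  expect_true(all(inst0$Z == 0))
  expect_error(build_instrument(co$X, co$dosages[, 0], NULL,
                                penalty_spec("l2", 1)), "empty")
})

test_that("instrument tracks the true polygenic signal", {
  co <- simulate_cohort(cohort_config(n_samples = 4000, n_variants = 100,
                                      h2_instrument = 0.3, seed = 57))
  inst <- build_instrument(co$X, co$dosages, NULL,
                           penalty_spec("l2", selection = "cross_validated"),
                           K = 5, seed = 58)
  target <- as.numeric(scale(co$dosages) %*% co$truth$beta_g)
  expect_gt(cor(inst$Z, target), 0.5)
})

test_that("out-of-fold prediction is less noise-contaminated than in-fold", {
  co <- simulate_cohort(cohort_config(n_samples = 800, n_variants = 120,
                                      seed = 59))
  noise <- co$X - co$config$depth_params$mtcn_scale *
    sqrt(co$truth$h2_instrument) *
    as.numeric(scale(scale(co$dosages) %*% co$truth$beta_g))
  inst <- build_instrument(co$X, co$dosages, NULL, penalty_spec("l2", 10),
                           K = 5, seed = 60)
  fit_all <- fit_penalized(co$X, co$dosages, matrix(1, 800, 1),
                           penalty_spec("l2", 10))
  z_in <- as.numeric(co$dosages %*% fit_all$beta)
  expect_lt(abs(cor(inst$Z, noise)), abs(cor(z_in, noise)))
})

test_that("chained-equations imputation has the donor-draw property", {
  co <- small_cohort(n = 300, m = 10, seed = 61, missing_rate = 0.15)
  dat <- cohort_phenotypes(co)
  imps <- mi_impute(dat, m = 3, maxit = 3, seed = 62)
  expect_length(imps, 3)
  for (v in names(dat)) {
    mis <- is.na(dat[[v]])
    if (!any(mis)) next
    obs <- dat[[v]][!mis]
    for (k in 1:3) {
      expect_false(anyNA(imps[[k]][[v]]))
      # tree learner: every imputed value is an observed donor value
      expect_true(all(imps[[k]][[v]][mis] %in% obs))
      # observed values untouched
      expect_identical(imps[[k]][[v]][!mis], obs)
    }
  }
  # deterministic given the seed; streams differ across imputations
  imps2 <- mi_impute(dat, m = 3, maxit = 3, seed = 62)
  expect_identical(imps, imps2)
  expect_false(identical(imps[[1]], imps[[2]]))
  # complete data: m identical copies
  full <- mi_impute(dat[complete.cases(dat), ], m = 2, seed = 63)
  expect_identical(full[[1]], full[[2]])
  allna <- dat; allna$X <- NA_real_
  expect_error(mi_impute(allna, m = 2), "all values missing")
})

test_that("causality regression isolates the instrument coefficient", {
  set.seed(64)
  n <- 1000
  Z <- rnorm(n)
  Y <- 0.2 * Z + rnorm(n, 0, 0.5)
  tc <- test_causality(Y, Z)
  expect_lt(abs(tc$estimate - 0.2), 2 * tc$se)
  # a covariate orthogonal to intercept and Z leaves the estimate unchanged
  w <- qr.resid(qr(cbind(1, Z)), rnorm(n))
  tc2 <- test_causality(Y, Z, cbind(w = w))
  expect_lt(abs(tc2$estimate - tc$estimate), 1e-10)
  expect_error(test_causality(Y, Z, cbind(Z, Z)), "rank deficient")
})

test_that("run_mr pools imputations and reduces cleanly to one dataset", {
  co <- small_cohort(n = 600, m = 30, seed = 65)
  fit <- run_mr(list(metsim = co), penalty = "both", selection = "fixed",
                lambda = 30, m_imputations = 4, maxit = 2, seed = 66)
  for (kind in c("l1", "l2")) {
    pk <- fit$penalties[[kind]]
    pooled <- pk$datasets$metsim$pooled
    # single dataset: meta equals the pooled result
    expect_equal(pk$meta$beta, pooled$beta)
    expect_equal(pk$meta$se, pooled$se)
    # Rubin df convention and the nonnegative between-variance property
    expect_equal(pooled$df, 2)
    expect_gte(pooled$se, sqrt(mean(pk$datasets$metsim$per_imputation$se^2)) -
                 1e-12)
  }
  s <- summary(fit)
  expect_s3_class(s, "data.frame")
  expect_true(all(c("penalty", "dataset", "beta", "se", "p") %in% names(s)))
  expect_named(coef(fit), c("l1", "l2"))
  expect_output(print(fit), "meta \\(IVW\\)")
  expect_error(run_mr(list(co), m_imputations = 1), "at least 2")
})

test_that("instrument satisfies the exclusion-restriction proxy when valid", {
  # no confounding, no causal effect: corr(Z, Y) centered on zero
  reps <- 20
  cors <- vapply(seq_len(reps), function(r) {
    co <- simulate_cohort(cohort_config(n_samples = 400, n_variants = 30,
                                        theta = 0,
                                        confounder_strengths = c(0, 0),
                                        missing_rate = 0, seed = 700 + r))
    inst <- build_instrument(co$X, co$dosages, NULL, penalty_spec("l2", 20),
                             K = 5, seed = 800 + r)
    cor(inst$Z, co$Y)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 3 / sqrt(400 * reps))
})

test_that("post hoc outlier rerun recovers planted gross outliers", {
  co <- small_cohort(n = 500, m = 20, seed = 67, missing_rate = 0)
  # plant gross outliers: extreme covariates (high leverage) + inflated Y
  planted <- 1:5
  co$W[planted, ] <- co$W[planted, ] + 6
  co$Y[planted] <- co$Y[planted] + 15
  fit <- run_mr(list(d = co), penalty = "l2", selection = "fixed",
                lambda = 30, m_imputations = 2, maxit = 1, seed = 68,
                prefilter_outliers = FALSE,
                alpha_screen = 1 - 1e-12)  # adjust all covariates
  ph <- posthoc_outlier_rerun(fit, list(d = co))
  expect_true(all(co$sample_id[planted] %in% ph$excluded$d))
  expect_s3_class(ph$rerun, "mtcn_mr")
  # clean data: the rerun estimate moves by less than half a pooled SE
  co2 <- small_cohort(n = 500, m = 20, seed = 69, missing_rate = 0)
  fit2 <- run_mr(list(d = co2), penalty = "l2", selection = "fixed",
                 lambda = 30, m_imputations = 2, maxit = 1, seed = 70,
                 prefilter_outliers = FALSE)
  ph2 <- posthoc_outlier_rerun(fit2, list(d = co2))
  shift <- abs(ph2$rerun$penalties$l2$meta$beta -
                 fit2$penalties$l2$meta$beta)
  expect_lt(shift, 0.5 * fit2$penalties$l2$meta$se)
})
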