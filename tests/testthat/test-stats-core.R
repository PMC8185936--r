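# Statistical engine: transforms, regressions, penalized fits, pooling,
# meta-analysis, multiplicity, distances.

test_that("inverse rank normal maps ranks to symmetric normal quantiles", {
  # oracle: high-precision normal quantile at (r - 0.5)/n
  expect_equal(inverse_rank_normal(c(10, 20, 30)),
               qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  expect_equal(round(inverse_rank_normal(c(10, 20, 30)), 4),
               c(-0.9674, 0, 0.9674))
  set.seed(1)
  x <- rnorm(101)
  expect_equal(sum(inverse_rank_normal(x)), 0, tolerance = 1e-12)
  expect_equal(order(inverse_rank_normal(x)), order(x))
  expect_warning(out <- inverse_rank_normal(c(5, 5)), "identical")
  expect_equal(out, c(0, 0))
  expect_error(inverse_rank_normal(3), "at least 2")
})

test_that("linear fit matches the normal-equations oracle", {
  set.seed(2)
  X <- toy_design(20, 3, seed = 2)
  y <- rnorm(20)
  fit <- fit_linear(y, X)
  expect_equal(unname(fit$coefficients),
               unname(drop(solve(crossprod(X), crossprod(X, y)))),
               tolerance = 1e-10)
  # residuals orthogonal to the design; leverage sums to p, within [0,1]
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8)
  expect_equal(sum(fit$leverage), 3, tolerance = 1e-10)
  expect_true(all(fit$leverage >= 0 & fit$leverage <= 1))
  expect_true(all(fit$p_values >= 0 & fit$p_values <= 1))
  # exact-fit and intercept-only identities
  fit2 <- fit_linear(X[, 2], X)
  expect_equal(unname(fit2$coefficients), c(0, 1, 0), tolerance = 1e-10)
  expect_lt(max(abs(fit2$residuals)), 1e-10)
  fit3 <- fit_linear(y, matrix(1, 20, 1))
  expect_equal(unname(fit3$coefficients), mean(y))
  expect_error(fit_linear(y, cbind(X, X[, 2])), "rank deficient")
  expect_error(fit_linear(y[1:3], toy_design(3, 4)), "n > p")
})

test_that("logistic fit recovers the closed-form 2x2 log odds ratio", {
  y <- rep(c(1, 0, 1, 0), c(10, 20, 30, 40))
  x <- rep(c(1, 1, 0, 0), c(10, 20, 30, 40))
  fit <- fit_logistic(y, cbind(1, x))
  expect_equal(unname(fit$coefficients[2]), log(10 * 40 / (20 * 30)),
               tolerance = 1e-6)
  expect_equal(round(unname(fit$coefficients[2]), 4), -0.4055)
  # identical outcome rates in both arms -> slope 0
  y2 <- rep(c(1, 0, 1, 0), c(10, 10, 20, 20))
  x2 <- rep(c(1, 0), c(20, 40))
  fit2 <- fit_logistic(y2, cbind(1, x2))
  expect_equal(unname(fit2$coefficients[2]), 0, tolerance = 1e-8)
  # cross-check against glm on a random instance
  set.seed(3)
  X <- toy_design(200, 3, seed = 3)
  yr <- rbinom(200, 1, plogis(X %*% c(-0.5, 1, -1)))
  fit3 <- fit_logistic(yr, X)
  ref <- glm.fit(X, yr, family = binomial())
  expect_equal(unname(fit3$coefficients), unname(ref$coefficients),
               tolerance = 1e-8)
  # complete separation is signalled, not fatal
  ys <- c(0, 0, 0, 1, 1, 1)
  xs <- c(1, 2, 3, 4, 5, 6)
  expect_warning(fs <- fit_logistic(ys, cbind(1, xs)), "converge")
  expect_false(fs$converged)
  expect_error(fit_logistic(rep(1, 10), matrix(1, 10, 1)), "both outcome")
})

test_that("penalized fit reduces to OLS at lambda 0 and obeys closed forms", {
  for (s in 1:3) {
    set.seed(s)
    P <- matrix(rnorm(50 * 8), 50, 8)
    F <- cbind(1, rnorm(50))
    y <- rnorm(50)
    for (kind in c("l1", "l2")) {
      f0 <- fit_penalized(y, P, F, penalty_spec(kind, 0))
      ols <- fit_linear(y, cbind(F, P))
      expect_lt(max(abs(c(f0$gamma, f0$beta) - ols$coefficients)), 1e-8)
    }
  }
  # ridge closed form on an orthonormal penalized block
  set.seed(4)
  P <- qr.Q(qr(matrix(rnorm(60 * 4), 60, 4)))
  y <- rnorm(60)
  f <- fit_penalized(y, P, NULL, penalty_spec("l2", 2.5), standardize = FALSE)
  expect_equal(f$beta, as.numeric(crossprod(P, y)) / (1 + 2.5),
               tolerance = 1e-10)
  # full shrinkage: beta ~ 0 and free coefficients ~ OLS on F alone
  F <- cbind(1, rnorm(60))
  fbig <- fit_penalized(y, P, F, penalty_spec("l1", 1e6))
  expect_lt(max(abs(fbig$beta)), 1e-10)
  expect_equal(unname(fbig$gamma),
               unname(fit_linear(y, F)$coefficients), tolerance = 1e-6)
  expect_error(penalty_spec("l1", -1), "nonnegative")
})

test_that("L1 path zeroes every coefficient beyond max |P'y|", {
  set.seed(5)
  P <- scale(matrix(rnorm(80 * 6), 80, 6))
  y <- rnorm(80)
  lam_max <- max(abs(crossprod(P, y)))
  f <- fit_penalized(y, P, NULL, penalty_spec("l1", lam_max * 1.001),
                     standardize = FALSE)
  expect_true(all(f$beta == 0))
  f2 <- fit_penalized(y, P, NULL, penalty_spec("l1", lam_max * 0.5),
                      standardize = FALSE)
  expect_gt(max(abs(f2$beta)), 0)
})

test_that("lasso solution agrees with glmnet on random instances", {
  skip_if_not_installed("glmnet")
  set.seed(6)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10)
  y <- X %*% c(1, -1, 0.5, rep(0, 7)) + rnorm(n)
  lam <- 8
  f <- fit_penalized(y, X, matrix(1, n, 1), penalty_spec("l1", lam),
                     standardize = FALSE)
  g <- glmnet::glmnet(X, y, alpha = 1, lambda = lam / n,
                      standardize = FALSE, thresh = 1e-12)
  expect_equal(f$beta, as.numeric(coef(g))[-1], tolerance = 1e-6)
})

test_that("Rubin pooling matches hand-computed oracles and conventions", {
  # identical estimates/variances: no between-imputation component
  r <- rubin_combine(rep(1.3, 5), rep(0.04, 5))
  expect_equal(r$between, 0)
  expect_equal(r$se, sqrt(0.04))
  expect_equal(r$beta, 1.3)
  # hand oracle: T = 0.04 + (4/3) * 0.04
  r3 <- rubin_combine(c(1.0, 1.2, 1.4), c(0.04, 0.04, 0.04))
  expect_equal(r3$beta, 1.2)
  expect_equal(r3$se^2, 0.04 + (4 / 3) * 0.04, tolerance = 1e-12)
  expect_equal(round(r3$se, 5), 0.30551)
  # df convention: m = 1000 imputations -> t reference with 998 df
  r1000 <- rubin_combine(rnorm(1000), rep(0.01, 1000))
  expect_equal(r1000$df, 998)
  # pooled SE is never below the mean within-imputation SE
  set.seed(7)
  for (i in 1:5) {
    est <- rnorm(10); v <- runif(10, 0.01, 0.05)
    rr <- rubin_combine(est, v)
    expect_gte(rr$se, sqrt(mean(v)) - 1e-12)
  }
  expect_error(rubin_combine(1, 0.1), "at least 2")
  expect_error(rubin_combine(c(1, 2), c(0.1, -0.1)), "positive")
})

test_that("fixed-effect IVW meta matches the weight arithmetic", {
  m <- meta_fixed_ivw(c(0.1, 0.3), c(0.05, 0.1))
  expect_equal(m$beta, (400 * 0.1 + 100 * 0.3) / 500)
  expect_equal(m$se, sqrt(1 / 500))
  expect_equal(round(m$se, 5), 0.04472)
  expect_equal(m$p, 2 * pnorm(-abs(m$beta / m$se)))
  single <- meta_fixed_ivw(0.2, 0.07)
  expect_equal(single$beta, 0.2)
  expect_equal(single$se, 0.07)
  twin <- meta_fixed_ivw(c(0.2, 0.2), c(0.07, 0.07))
  expect_equal(twin$beta, 0.2)
  expect_equal(twin$se, 0.07 / sqrt(2))
  expect_error(meta_fixed_ivw(0.1, -1), "positive")
})

test_that("DerSimonian-Laird meta matches the hand-computed oracle", {
  # w = (100, 100): Q = 50, tau2 = (50 - 1) / (200 - 100) = 0.49
  m <- meta_random_dl(c(0, 1), c(0.1, 0.1))
  expect_equal(m$Q, 50)
  expect_equal(m$tau2, 0.49)
  expect_equal(m$beta, 0.5)
  expect_equal(m$se, sqrt(1 / (2 / (0.01 + 0.49))))
  # homogeneous studies collapse to the fixed-effect result
  hom <- meta_random_dl(c(0.2, 0.21), c(0.1, 0.1))
  fix <- meta_fixed_ivw(c(0.2, 0.21), c(0.1, 0.1))
  expect_equal(hom$tau2, 0)
  expect_equal(hom$beta, fix$beta)
  expect_equal(hom$se, fix$se)
  expect_equal(meta_random_dl(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.3))$beta, 0.3)
})

test_that("meta-analysis estimates agree with metafor", {
  skip_if_not_installed("metafor")
  set.seed(8)
  b <- rnorm(6); s <- runif(6, 0.05, 0.3)
  fe <- metafor::rma(yi = b, sei = s, method = "FE")
  me <- meta_fixed_ivw(b, s)
  expect_equal(me$beta, as.numeric(fe$beta), tolerance = 1e-10)
  expect_equal(me$se, fe$se, tolerance = 1e-10)
  dl <- metafor::rma(yi = b, sei = s, method = "DL")
  md <- meta_random_dl(b, s)
  expect_equal(md$tau2, dl$tau2, tolerance = 1e-8)
  expect_equal(md$beta, as.numeric(dl$beta), tolerance = 1e-8)
  expect_equal(md$se, dl$se, tolerance = 1e-8)
})

test_that("q-values reduce to Benjamini-Hochberg at pi0 = 1", {
  q <- qvalues_bh_storey(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
  expect_equal(q$q_values, rep(0.04, 4))
  # permutation invariance
  set.seed(9)
  p <- runif(50)
  perm <- sample(50)
  q1 <- qvalues_bh_storey(p, pi0 = 1)$q_values
  q2 <- qvalues_bh_storey(p[perm], pi0 = 1)$q_values
  expect_equal(q2, q1[perm])
  # BH cross-check against p.adjust
  expect_equal(q1, p.adjust(p, "BH"), tolerance = 1e-12)
  # monotone in p-value rank
  expect_true(all(diff(q1[order(p)]) >= -1e-12))
  # all p = 1: pi0 estimate is 1 and all q are 1
  qa <- qvalues_bh_storey(rep(1, 20))
  expect_equal(qa$pi0, 1)
  expect_equal(qa$q_values, rep(1, 20))
  expect_error(qvalues_bh_storey(c(0.5, 1.2)), "0, 1")
})

test_that("Storey pi0 is near 1 for uniform null p-values", {
  set.seed(10)
  q <- qvalues_bh_storey(runif(1000))
  expect_gte(q$pi0, 0.8)
  expect_lte(q$pi0, 1.0)
})

test_that("Bonferroni threshold is alpha over the test count", {
  expect_equal(signif(bonferroni_threshold(23105, 0.05), 4), 2.164e-6)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(100, 0.05), 5e-4)
  expect_error(bonferroni_threshold(0), "at least 1")
})

test_that("Mahalanobis distance honours the covariance metric", {
  mu <- c(0, 0)
  S <- diag(c(2, 0.5))
  expect_equal(unname(mahalanobis_distances(rbind(mu), mu, S)), 0)
  expect_equal(unname(mahalanobis_distances(rbind(c(2, 1)), mu, S)), 2)
  # identity covariance gives Euclidean distance
  x <- matrix(rnorm(20), 10, 2)
  expect_equal(mahalanobis_distances(x, c(0, 0), diag(2)),
               sqrt(rowSums(x^2)))
  expect_error(mahalanobis_distances(x, c(0, 0), matrix(c(1, 1, 1, 1), 2)),
               "singular")
})
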