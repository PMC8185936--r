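# Shared statistical engine: regressions, penalized fits, transforms,
# pooling, meta-analysis, multiplicity control, outlier diagnostics.

#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles through their (tie-averaged)
#' ranks, `qnorm((r - 0.5) / n)`. The offset 0.5 makes the output symmetric
#' with exact mean zero for tie-free input. Non-finite entries are left as
#' `NA` and ranks are computed among the finite values only.
#'
#' @param x numeric vector with at least two finite values.
#' @return numeric vector of the same length; monotone in `x`.
#' @export
inverse_rank_normal <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2L) stop("inverse_rank_normal() needs at least 2 finite values")
  v <- x[ok]
  if (length(unique(v)) == 1L)
    warning("all values identical: inverse_rank_normal() output is degenerate")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 0.5) / length(v))
  out
}

new_regression_fit <- function(coefficients, standard_errors, statistics,
                               p_values, residuals, std_residuals, leverage,
                               family, n, p, converged = TRUE) {
  structure(list(
    coefficients = coefficients, standard_errors = standard_errors,
    statistics = statistics, p_values = p_values, residuals = residuals,
    std_residuals = std_residuals, leverage = leverage,
    family = family, n = n, p = p, converged = converged
  ), class = "regression_fit")
}

#' Ordinary least squares fit
#'
#' OLS with t-based p-values; residuals, standardized residuals and the
#' hat-matrix diagonal (leverage) are returned for outlier diagnostics.
#'
#' @param y numeric response.
#' @param design numeric model matrix (supply the intercept column yourself).
#' @return a `regression_fit` list: coefficients, standard_errors,
#'   statistics, p_values, residuals, std_residuals, leverage, family, n, p.
#' @export
fit_linear <- function(y, design) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (length(y) != n) stop("length(y) must match nrow(design)")
  if (n <= p) stop("fit_linear() requires n > p")
  qrx <- qr(design)
  if (qrx$rank < p) stop("design matrix is rank deficient")
  beta <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  lev <- rowSums(qr.Q(qrx)[, seq_len(p), drop = FALSE]^2)
  s2 <- sum(res^2) / (n - p)
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(xtx_inv) * s2, 0))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  sr <- res / sqrt(pmax(s2 * (1 - lev), .Machine$double.eps))
  new_regression_fit(beta, se, tval, pval, res, sr, lev, "linear", n, p)
}

#' Logistic regression fit
#'
#' Maximum likelihood by iteratively reweighted least squares with Wald z
#' p-values. Quasi-complete separation is signalled (not an error) by
#' `converged = FALSE` when the fit fails to converge or any coefficient
#' exceeds 15 on the standardized design scale.
#'
#' @param y binary 0/1 response (both classes must be present).
#' @param design numeric model matrix including the intercept.
#' @return a `regression_fit` with Pearson residuals and their standardized
#'   form, and IRLS hat values as leverage.
#' @export
fit_logistic <- function(y, design) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("fit_logistic() requires both outcome classes")
  fit <- suppressWarnings(
    stats::glm.fit(design, y, family = stats::binomial())
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  WX <- design * sqrt(w)
  qrx <- qr(WX)
  if (qrx$rank < p) stop("design matrix is rank deficient")
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(xtx_inv))
  lev <- rowSums(qr.Q(qrx)[, seq_len(p), drop = FALSE]^2)
  pearson <- (y - mu) / sqrt(w)
  sr <- pearson / sqrt(pmax(1 - lev, .Machine$double.eps))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  col_sd <- apply(design, 2, stats::sd)
  scale_chk <- ifelse(col_sd > 0, col_sd, 1)
  converged <- isTRUE(fit$converged) && all(abs(beta * scale_chk) <= 15)
  if (!converged)
    warning("logistic fit did not converge (possible complete separation)")
  new_regression_fit(beta, se, z, pval, y - mu, sr, lev,
                     "logistic", n, p, converged = converged)
}

#' Penalty specification for penalized fits
#'
#' @param kind `"l1"` (lasso) or `"l2"` (ridge).
#' @param lambda nonnegative penalty weight; required when
#'   `selection = "fixed"`, used as an upper anchor otherwise.
#' @param selection `"fixed"` or `"cross_validated"` (inner 5-fold CV with
#'   the one-standard-error rule, applied where the caller builds instruments).
#' @return a `penalty_spec` list.
#' @export
penalty_spec <- function(kind = c("l1", "l2"), lambda = NULL,
                         selection = c("fixed", "cross_validated")) {
  kind <- match.arg(kind)
  selection <- match.arg(selection)
  if (selection == "fixed") {
    if (is.null(lambda)) stop("fixed selection requires a lambda")
    if (lambda < 0) stop("lambda must be nonnegative")
  }
  structure(list(kind = kind, lambda = lambda, selection = selection),
            class = "penalty_spec")
}

# Soft-threshold operator for the lasso coordinate updates.
soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Coordinate descent for min 1/2 ||y - P b||^2 + lambda ||b||_1 using the
# Gram form; convergence when max |coefficient change| < tol.
lasso_cd <- function(gram, cty, lambda, beta0 = NULL,
                     tol = 1e-7, max_sweeps = 1e5) {
  m <- length(cty)
  beta <- if (is.null(beta0)) numeric(m) else beta0
  gb <- as.numeric(gram %*% beta)
  for (sweep in seq_len(max_sweeps)) {
    delta_max <- 0
    for (j in seq_len(m)) {
      cj <- cty[j] - gb[j] + gram[j, j] * beta[j]
      bj <- soft_threshold(cj, lambda) / gram[j, j]
      d <- bj - beta[j]
      if (d != 0) {
        gb <- gb + gram[, j] * d
        beta[j] <- bj
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
  }
  beta
}

#' Penalized regression with an unpenalized free block
#'
#' Minimizes `1/2 ||y - P b - F g||^2 + lambda * pen(b)` with
#' `pen = ||b||_1` (L1) or `1/2 ||b||_2^2` (L2); the free block `F` is never
#' penalized. With `standardize = TRUE` the penalized columns are rescaled to
#' unit variance internally so that `lambda` is comparable across variants,
#' and coefficients are reported back on the original scale. The free block
#' is profiled out exactly (Frisch-Waugh): `y` and `P` are residualized on
#' `F`, the penalized problem is solved, and `g` is recovered by OLS.
#'
#' @param y numeric response.
#' @param P matrix of penalized columns.
#' @param F matrix of unpenalized columns (or `NULL`); include the intercept
#'   here if one is wanted.
#' @param penalty a [penalty_spec()] with a fixed lambda.
#' @param standardize scale penalized columns to unit variance before
#'   penalization (default). `FALSE` solves the stated objective on the
#'   columns as given.
#' @return list with `beta` (penalized, original scale), `gamma` (free),
#'   `lambda`, `kind`.
#' @export
fit_penalized <- function(y, P, F = NULL, penalty, standardize = TRUE) {
  P <- as.matrix(P)
  n <- nrow(P); m <- ncol(P)
  if (penalty$selection != "fixed")
    stop("fit_penalized() needs a fixed lambda; use build_instrument() for CV")
  lambda <- penalty$lambda
  if (lambda < 0) stop("lambda must be nonnegative")
  s <- rep(1, m)
  if (standardize) {
    s <- apply(P, 2, stats::sd)
    if (any(s == 0)) stop("constant penalized column cannot be standardized")
    P <- sweep(P, 2, s, "/")
  }
  if (!is.null(F)) {
    F <- as.matrix(F)
    qrf <- qr(F)
    if (qrf$rank < ncol(F)) stop("free block is rank deficient")
    yr <- qr.resid(qrf, y)
    Pr <- qr.resid(qrf, P)
  } else {
    yr <- y; Pr <- P
  }
  gram <- crossprod(Pr)
  cty <- as.numeric(crossprod(Pr, yr))
  if (lambda == 0) {
    b <- qr.coef(qr(Pr), yr)
  } else if (penalty$kind == "l2") {
    b <- solve(gram + diag(lambda, m), cty)
  } else {
    b <- lasso_cd(gram, cty, lambda)
  }
  beta <- b / s
  gamma <- NULL
  if (!is.null(F)) {
    P_orig <- sweep(P, 2, s, "*")
    gamma <- qr.coef(qrf, y - as.numeric(P_orig %*% beta))
  }
  list(beta = as.numeric(beta), gamma = gamma,
       lambda = lambda, kind = penalty$kind)
}

#' Pool estimates across multiple imputations by Rubin's rules
#'
#' Point estimate is the mean across imputations; total variance combines the
#' mean within-imputation variance with the between-imputation variance
#' inflated by `(1 + 1/m)`. The default degrees of freedom follow the
#' pipeline convention `m - 2` (a t reference with 998 df at m = 1000); the
#' Barnard-Rubin small-sample adjustment is available via `df_method`.
#'
#' @param estimates per-imputation point estimates (length m >= 2).
#' @param variances per-imputation squared standard errors.
#' @param df_method `"m-2"` (default) or `"barnard-rubin"`.
#' @param dfcom complete-data degrees of freedom for Barnard-Rubin
#'   (default `Inf` reduces it to the classic large-sample df).
#' @return list(beta, se, df, p, within, between, m).
#' @export
rubin_combine <- function(estimates, variances,
                          df_method = c("m-2", "barnard-rubin"),
                          dfcom = Inf) {
  df_method <- match.arg(df_method)
  m <- length(estimates)
  if (m < 2L) stop("rubin_combine() requires at least 2 imputations")
  if (length(variances) != m) stop("estimates and variances differ in length")
  if (any(variances <= 0)) stop("variances must be positive")
  beta <- mean(estimates)
  wbar <- mean(variances)
  b <- stats::var(estimates)
  total <- wbar + (1 + 1 / m) * b
  se <- sqrt(total)
  if (df_method == "m-2") {
    df <- m - 2
  } else {
    # Barnard & Rubin (1999): combine the classic df with the observed-data df.
    r <- (1 + 1 / m) * b / wbar
    df_old <- (m - 1) * (1 + 1 / r)^2
    if (is.finite(dfcom)) {
      gamma_frac <- (1 + 1 / m) * b / total
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - gamma_frac)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  }
  p <- if (df >= 1) 2 * stats::pt(-abs(beta / se), df = df) else NA_real_
  list(beta = beta, se = se, df = df, p = p,
       within = wbar, between = b, m = m)
}

new_meta_estimate <- function(beta, se, method, tau2, Q, k) {
  z <- beta / se
  structure(list(beta = beta, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 method = method, tau2 = tau2, Q = Q, k = k),
            class = "meta_estimate")
}

#' Fixed-effect inverse-variance weighted meta-analysis
#'
#' Weights `1/se^2`; pooled effect tested with a two-sided Z test.
#'
#' @param betas study effect estimates.
#' @param ses study standard errors (all positive).
#' @return a `meta_estimate`: beta, se, z, p, method, tau2 (0), Q, k.
#' @export
meta_fixed_ivw <- function(betas, ses) {
  k <- length(betas)
  if (k < 1L) stop("meta_fixed_ivw() needs at least one study")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  Q <- sum(w * (betas - beta)^2)
  new_meta_estimate(beta, se, "fixed_ivw", 0, Q, k)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, then
#' re-weighting with `1/(se^2 + tau2)`. Homogeneous studies (Q <= k-1)
#' reduce to the fixed-effect result.
#'
#' @inheritParams meta_fixed_ivw
#' @return a `meta_estimate` with `method = "random_dl"`.
#' @export
meta_random_dl <- function(betas, ses) {
  k <- length(betas)
  if (k < 2L) stop("meta_random_dl() needs at least two studies")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  beta_f <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - beta_f)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (ses^2 + tau2)
  beta <- sum(wr * betas) / sum(wr)
  se <- sqrt(1 / sum(wr))
  new_meta_estimate(beta, se, "random_dl", tau2, Q, k)
}

#' q-values: Benjamini-Hochberg with Storey's pi0 correction
#'
#' `q_i = pi0 * min_{j: p_j >= p_i} (n p_j / rank_j)` clipped to \[0, 1\].
#' `pi0` is estimated on the lambda grid 0.05, 0.10, ..., 0.95 with a cubic
#' smoothing spline evaluated at the largest lambda, clipped to (0, 1\];
#' forcing `pi0 = 1` reduces the procedure to classical BH.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param pi0 optional fixed null proportion; `NULL` (default) estimates it.
#' @param lambda grid for the Storey estimator.
#' @return list(p_values, q_values, pi0) of class `q_table`.
#' @export
qvalues_bh_storey <- function(p_values, pi0 = NULL,
                              lambda = seq(0.05, 0.95, by = 0.05)) {
  p <- p_values
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1] with no missing values")
  n <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(cummin(n * p[o] / rank(p, ties.method = "max")[o]), 1)[ro]
  q <- pmin(pi0 * q, 1)
  structure(list(p_values = p, q_values = q, pi0 = pi0), class = "q_table")
}

#' Bonferroni significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate in (0, 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / n_tests
}

#' Mahalanobis distances
#'
#' `d_i = sqrt((x_i - mu)' Sigma^-1 (x_i - mu))` for each row.
#'
#' @param rows numeric matrix of observations (rows).
#' @param center mean vector `mu` (defaults to column means).
#' @param covariance symmetric positive-definite `Sigma` (defaults to the
#'   sample covariance of `rows`).
#' @return numeric vector of distances.
#' @export
mahalanobis_distances <- function(rows, center = colMeans(rows),
                                  covariance = stats::cov(rows)) {
  rows <- as.matrix(rows)
  if (!isSymmetric(unname(covariance), tol = 1e-8))
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) stop("covariance is singular")
  sqrt(stats::mahalanobis(rows, center, covariance))
}
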