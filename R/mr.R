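# Penalized-instrument Mendelian randomization of log MT-CN on log insulin.
#
# The exposure X (log raw MT-CN) is regressed on the genotype matrix G with
# an L1 or L2 penalty, adjusting without penalty for covariate sets A
# (outcome-associated) and B (exposure-associated conditional on A). The
# instrument Z is predicted out of fold (K = 5) so that each sample's Z uses
# only weights fit without it. The causality test regresses Y on Z adjusting
# for every covariate with a first-order association with Z or Y. Missing
# phenotypes are multiply imputed; the per-imputation estimates are pooled by
# Rubin's rules and tested with a t reference (df = m - 2); datasets are
# combined by fixed-effect inverse-variance weighting with a Z test.

#' Partition covariates into outcome- and exposure-associated sets
#'
#' Set A holds the columns of `W` marginally associated with the outcome `Y`
#' at `alpha_screen`; set B holds the remaining columns associated with the
#' exposure `X` in a regression adjusting for all of A. A takes precedence:
#' a covariate associated with both lands in A only. Screening uses
#' complete-case rows; constant columns are dropped with a warning.
#'
#' @param W covariate matrix with column names.
#' @param X exposure vector.
#' @param Y outcome vector.
#' @param alpha_screen screening threshold; default `0.05 / ncol(W)`.
#' @return a `covariate_partition` list: set_A, set_B, alpha_screen.
#' @export
partition_covariates <- function(W, X, Y, alpha_screen = NULL) {
  W <- as.matrix(W)
  if (ncol(W) == 0L) stop("W has zero columns")
  if (is.null(alpha_screen)) alpha_screen <- 0.05 / ncol(W)
  cc <- stats::complete.cases(W, X, Y)
  Wc <- W[cc, , drop = FALSE]; Xc <- X[cc]; Yc <- Y[cc]
  keep <- apply(Wc, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(Wc)[!keep], collapse = ", "))
    Wc <- Wc[, keep, drop = FALSE]
  }
  p_y <- vapply(seq_len(ncol(Wc)), function(j)
    fit_linear(Yc, cbind(1, Wc[, j]))$p_values[2], numeric(1))
  set_A <- colnames(Wc)[p_y < alpha_screen]
  rest <- setdiff(colnames(Wc), set_A)
  set_B <- character(0)
  for (v in rest) {
    des <- cbind(1, Wc[, set_A, drop = FALSE], Wc[, v])
    p <- fit_linear(Xc, des)$p_values[ncol(des)]
    if (p < alpha_screen) set_B <- c(set_B, v)
  }
  structure(list(set_A = set_A, set_B = set_B, alpha_screen = alpha_screen),
            class = "covariate_partition")
}

# Inner cross-validation for the instrument penalty weight: lambda grid
# anchored at max |P'y| after standardization, one-standard-error rule.
cv_choose_lambda <- function(y, P, F, kind, nfolds = 5, nlambda = 12,
                             seed = 1L) {
  n <- length(y)
  s <- apply(P, 2, stats::sd)
  Ps <- sweep(P, 2, s, "/")
  qrf0 <- qr(F)
  lam_max <- max(abs(crossprod(qr.resid(qrf0, Ps), qr.resid(qrf0, y))))
  expo <- if (kind == "l1") seq(0, -3, length.out = nlambda)
          else seq(0.5, -3.5, length.out = nlambda)
  grid <- lam_max * 10^expo
  set.seed(seed)
  fold <- sample(rep_len(seq_len(nfolds), n))
  mse <- matrix(NA_real_, nlambda, nfolds)
  for (f in seq_len(nfolds)) {
    tr <- fold != f; te <- !tr
    qrf <- qr(F[tr, , drop = FALSE])
    yr <- qr.resid(qrf, y[tr])
    Pr <- qr.resid(qrf, Ps[tr, , drop = FALSE])
    gram <- crossprod(Pr)
    cty <- as.numeric(crossprod(Pr, yr))
    b <- numeric(ncol(Ps))
    for (li in seq_len(nlambda)) {
      lam <- grid[li]
      b <- if (kind == "l2") solve(gram + diag(lam, ncol(gram)), cty)
           else lasso_cd(gram, cty, lam, beta0 = b)
      gam <- qr.coef(qrf, y[tr] - as.numeric(Ps[tr, , drop = FALSE] %*% b))
      pred <- as.numeric(F[te, , drop = FALSE] %*% gam) +
        as.numeric(Ps[te, , drop = FALSE] %*% b)
      mse[li, f] <- mean((y[te] - pred)^2)
    }
  }
  cvm <- rowMeans(mse)
  cvse <- apply(mse, 1, stats::sd) / sqrt(nfolds)
  i_min <- which.min(cvm)
  ok <- which(cvm <= cvm[i_min] + cvse[i_min])
  grid[min(ok)]  # grid is decreasing in index 1? no: decreasing lambda; min index = largest lambda
}

#' Build a penalized genetic instrument with out-of-fold prediction
#'
#' Samples are split into `K` folds; for each fold j the exposure is
#' regressed on the genotypes (penalized) and the free covariate block A u B
#' (unpenalized) using the samples outside j, and the instrument value of
#' every sample in fold j is its genotype row times those held-out weights.
#' With `penalty$selection = "cross_validated"` the penalty weight is chosen
#' per training fold by inner 5-fold cross-validation with the
#' one-standard-error rule.
#'
#' @param X exposure vector (complete).
#' @param G dosage matrix (samples x variants).
#' @param W_AB unpenalized covariate matrix (or `NULL`); an intercept is
#'   always added.
#' @param penalty a [penalty_spec()].
#' @param K number of folds (default 5).
#' @param seed integer seed for fold assignment and inner CV.
#' @return an `instrument_model`: fold_assignment, beta_G_per_fold (variants
#'   x K), beta_G_bar, Z, lambdas, penalty.
#' @export
build_instrument <- function(X, G, W_AB = NULL, penalty, K = 5, seed = 1L) {
  G <- as.matrix(G)
  n <- nrow(G)
  if (ncol(G) == 0L) stop("empty genotype matrix")
  if (K > n) stop("more folds than samples")
  if (K < 2L) stop("K must be at least 2")
  F <- cbind(intercept = rep(1, n))
  if (!is.null(W_AB) && NCOL(W_AB) > 0) F <- cbind(F, as.matrix(W_AB))
  if (n <= ncol(F)) stop("free block has too many columns for n")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(K), n))
  beta_folds <- matrix(0, ncol(G), K,
                       dimnames = list(colnames(G), paste0("fold", seq_len(K))))
  lambdas <- numeric(K)
  Z <- numeric(n)
  for (j in seq_len(K)) {
    tr <- fold != j
    lam <- if (penalty$selection == "cross_validated") {
      cv_choose_lambda(X[tr], G[tr, , drop = FALSE], F[tr, , drop = FALSE],
                       penalty$kind, seed = seed + j)
    } else penalty$lambda
    fit <- fit_penalized(X[tr], G[tr, , drop = FALSE], F[tr, , drop = FALSE],
                         penalty_spec(penalty$kind, lam, "fixed"))
    beta_folds[, j] <- fit$beta
    lambdas[j] <- lam
    Z[fold == j] <- as.numeric(G[fold == j, , drop = FALSE] %*% fit$beta)
  }
  structure(list(fold_assignment = fold, beta_G_per_fold = beta_folds,
                 beta_G_bar = rowMeans(beta_folds), Z = Z,
                 lambdas = lambdas, penalty = penalty),
            class = "instrument_model")
}

#' Classify covariates for the causality test
#'
#' Each covariate is tested marginally against the instrument `Z` and the
#' outcome `Y` at `alpha_screen`. Set I has a first-order association with
#' neither and is never adjusted; sets II (both), III (Z only) and IV
#' (Y only) are adjusted for in the causality test.
#'
#' @inheritParams partition_covariates
#' @param Z instrument values.
#' @return a `causality_adjustment_sets` list: set_I..set_IV, adjusted,
#'   alpha_screen.
#' @export
classify_for_causality <- function(W, Z, Y, alpha_screen = NULL) {
  W <- as.matrix(W)
  if (ncol(W) == 0L) stop("W has zero columns")
  if (is.null(alpha_screen)) alpha_screen <- 0.05 / ncol(W)
  cc <- stats::complete.cases(W, Z, Y)
  Wc <- W[cc, , drop = FALSE]; Zc <- Z[cc]; Yc <- Y[cc]
  keep <- apply(Wc, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(Wc)[!keep], collapse = ", "))
    Wc <- Wc[, keep, drop = FALSE]
  }
  p_of <- function(resp) vapply(seq_len(ncol(Wc)), function(j)
    fit_linear(resp, cbind(1, Wc[, j]))$p_values[2], numeric(1))
  az <- p_of(Zc) < alpha_screen
  ay <- p_of(Yc) < alpha_screen
  nm <- colnames(Wc)
  sets <- list(set_I = nm[!az & !ay], set_II = nm[az & ay],
               set_III = nm[az & !ay], set_IV = nm[!az & ay])
  structure(c(sets, list(adjusted = nm[az | ay], alpha_screen = alpha_screen)),
            class = "causality_adjustment_sets")
}

# Bayesian linear regression imputation draw (chained-equations fallback).
norm_draw <- function(y_obs, x_obs, x_mis) {
  X <- cbind(1, as.matrix(x_obs))
  Xm <- cbind(1, as.matrix(x_mis))
  p <- ncol(X); n <- nrow(X)
  xtx <- crossprod(X) + diag(1e-8, p)
  xtx_inv <- solve(xtx)
  beta_hat <- xtx_inv %*% crossprod(X, y_obs)
  rss <- sum((y_obs - X %*% beta_hat)^2)
  df <- max(n - p, 1)
  sigma2 <- rss / stats::rchisq(1, df)
  beta_star <- beta_hat +
    t(chol(sigma2 * (xtx_inv + t(xtx_inv)) / 2)) %*% stats::rnorm(p)
  as.numeric(Xm %*% beta_star) + stats::rnorm(nrow(Xm), 0, sqrt(sigma2))
}

draw_one <- function(pool) pool[sample.int(length(pool), 1L)]

#' Chained-equations multiple imputation with regression-tree learner
#'
#' Missing values are imputed by fully conditional specification: each
#' incomplete variable is modelled on all others with a regression tree
#' (maximum depth 5, minimum node size 10) and imputations are drawn from
#' the observed donor values in the matched terminal node, so every imputed
#' value is an observed value of that variable. Variables with fewer than
#' `min_tree_n` observed rows fall back to a Bayesian linear regression with
#' a posterior noise draw. `m` independent streams are seeded
#' deterministically from `seed`.
#'
#' @param data data.frame of numeric variables with `NA` for missing.
#' @param m number of completed tables.
#' @param maxit chained-equation sweeps per imputation.
#' @param seed integer seed.
#' @param min_tree_n minimum observed rows for the tree learner.
#' @return list of `m` completed data.frames.
#' @export
mi_impute <- function(data, m, maxit = 25, seed = 1L, min_tree_n = 50) {
  data <- as.data.frame(data)
  miss <- is.na(data)
  if (any(colSums(!miss) == 0)) stop("variable with all values missing")
  if (!any(miss)) return(replicate(m, data, simplify = FALSE))
  n_mis <- colSums(miss)
  vars <- names(data)[n_mis > 0]
  vars <- vars[order(n_mis[vars])]
  ctrl <- rpart::rpart.control(maxdepth = 5, minbucket = 10, cp = 1e-4,
                               xval = 0)
  out <- vector("list", m)
  for (k in seq_len(m)) {
    set.seed((seed + 131L * k) %% .Machine$integer.max)
    comp <- data
    for (v in vars) {
      mi <- miss[, v]
      pool <- data[[v]][!mi]
      comp[[v]][mi] <- pool[sample.int(length(pool), sum(mi), replace = TRUE)]
    }
    for (it in seq_len(maxit)) {
      for (v in vars) {
        mi <- miss[, v]
        preds <- setdiff(names(data), v)
        y_obs <- data[[v]][!mi]
        x_obs <- comp[!mi, preds, drop = FALSE]
        x_mis <- comp[mi, preds, drop = FALSE]
        if (length(y_obs) >= min_tree_n) {
          dtr <- data.frame(..y.. = y_obs, x_obs, check.names = FALSE)
          fit <- rpart::rpart(..y.. ~ ., data = dtr, method = "anova",
                              control = ctrl)
          node_obs <- stats::predict(fit)
          node_mis <- stats::predict(fit, newdata = x_mis)
          imp <- vapply(node_mis, function(nd) {
            donors <- y_obs[node_obs == nd]
            if (!length(donors)) donors <- y_obs
            draw_one(donors)
          }, numeric(1))
        } else {
          imp <- norm_draw(y_obs, x_obs, x_mis)
        }
        comp[[v]][mi] <- imp
      }
    }
    out[[k]] <- comp
  }
  out
}

#' Causality test: outcome on instrument with adjustment
#'
#' OLS of `Y` on `Z` plus the adjusted covariates (with intercept); returns
#' the instrument coefficient and its standard error, plus the full fit for
#' outlier diagnostics.
#'
#' @param Y outcome (complete, post-imputation).
#' @param Z instrument values.
#' @param adjust covariate matrix to adjust for (or `NULL`).
#' @return list(estimate, se, fit).
#' @export
test_causality <- function(Y, Z, adjust = NULL) {
  design <- cbind(intercept = 1, Z = Z)
  if (!is.null(adjust) && NCOL(adjust) > 0)
    design <- cbind(design, as.matrix(adjust))
  fit <- fit_linear(Y, design)
  list(estimate = unname(fit$coefficients[2]),
       se = unname(fit$standard_errors[2]), fit = fit)
}

as_mr_dataset <- function(x, name) {
  if (inherits(x, "synthetic_cohort")) {
    X <- log(x$mtcn_raw)
    X[x$missing_mask$X] <- NA
    Y <- x$Y
    Y[x$missing_mask$Y] <- NA
    W <- x$W
    for (v in colnames(W))
      if (v %in% names(x$missing_mask)) W[x$missing_mask[[v]], v] <- NA
    list(name = if (is.null(x$name)) name else x$name,
         X = X, Y = Y, W = W, G = x$dosages, sample_id = x$sample_id)
  } else {
    if (is.null(x$sample_id)) x$sample_id <- sprintf("s%05d", seq_along(x$X))
    if (is.null(x$name)) x$name <- name
    x
  }
}

mr_prefilter <- function(ds, sd_threshold = 6, md_alpha = 1e-6) {
  tab <- cbind(X = ds$X, Y = ds$Y, ds$W)
  cc <- which(stats::complete.cases(tab))
  if (length(cc) < 10L) return(character(0))
  sub <- tab[cc, , drop = FALSE]
  excl_pca <- pca_outlier_iterate(sub, sd_threshold = sd_threshold)
  md <- tryCatch(mahalanobis_distances(sub), error = function(e) NULL)
  excl_md <- if (is.null(md)) integer(0) else
    which(md^2 > stats::qchisq(1 - md_alpha, df = ncol(sub)))
  ds$sample_id[cc[union(excl_pca, excl_md)]]
}

run_mr_one <- function(ds, kind, selection, lambda, m_imputations, folds,
                       alpha_screen, maxit, seed, df_method) {
  pen <- if (selection == "fixed") penalty_spec(kind, lambda, "fixed")
         else penalty_spec(kind, selection = "cross_validated")
  imps <- mi_impute(data.frame(X = ds$X, Y = ds$Y, ds$W, check.names = FALSE),
                    m = m_imputations, maxit = maxit, seed = seed)
  est <- se <- numeric(m_imputations)
  diags <- vector("list", m_imputations)
  n_adj <- integer(m_imputations)
  for (i in seq_len(m_imputations)) {
    d <- imps[[i]]
    W_i <- as.matrix(d[, -(1:2), drop = FALSE])
    part <- partition_covariates(W_i, d$X, d$Y, alpha_screen)
    W_AB <- W_i[, c(part$set_A, part$set_B), drop = FALSE]
    inst <- build_instrument(d$X, ds$G, W_AB, pen, K = folds,
                             seed = (seed + 977L * i) %% .Machine$integer.max)
    cls <- classify_for_causality(W_i, inst$Z, d$Y, alpha_screen)
    tc <- test_causality(d$Y, inst$Z,
                         W_i[, cls$adjusted, drop = FALSE])
    est[i] <- tc$estimate; se[i] <- tc$se
    n_adj[i] <- length(cls$adjusted)
    diags[[i]] <- data.frame(sample_id = ds$sample_id,
                             std_residual = tc$fit$std_residuals,
                             leverage = tc$fit$leverage)
  }
  pooled <- rubin_combine(est, se^2, df_method = df_method)
  list(per_imputation = data.frame(imputation = seq_len(m_imputations),
                                   estimate = est, se = se,
                                   n_adjusted = n_adj),
       pooled = pooled, diagnostics = diags, n = length(ds$X))
}

#' Run the full Mendelian randomization procedure
#'
#' For each dataset and penalty: pre-analysis multivariate outlier removal
#' (iterated PCA plus Mahalanobis distance on the complete-case quantitative
#' traits), `m_imputations` chained-equation imputations, and within each
#' imputation covariate partitioning, out-of-fold instrument construction,
#' covariate classification and the causality regression; the per-imputation
#' estimates are pooled by Rubin's rules (t test, df = m - 2), and the
#' per-dataset pooled effects are combined by fixed-effect inverse-variance
#' weighted meta-analysis with a Z test.
#'
#' Variants are pre-filtered to minor allele frequency `>= maf_min`.
#'
#' @param datasets a list of datasets: `synthetic_cohort` objects (the
#'   exposure is taken as the log of raw, batch-shifted MT-CN) or lists with
#'   fields `X`, `Y`, `W`, `G` and optional `name`/`sample_id`.
#' @param penalty `"l1"`, `"l2"` or `"both"`.
#' @param selection `"cross_validated"` (default) or `"fixed"`.
#' @param lambda penalty weight when `selection = "fixed"`.
#' @param m_imputations number of imputations (>= 2).
#' @param folds outer folds for the instrument (default 5).
#' @param alpha_screen covariate screening threshold; default Bonferroni
#'   `0.05 / ncol(W)`.
#' @param maf_min variant minor-allele-frequency filter.
#' @param maxit chained-equation sweeps per imputation.
#' @param seed integer seed driving every random step.
#' @param prefilter_outliers run the pre-analysis outlier removal.
#' @param df_method Rubin df convention, see [rubin_combine()].
#' @param exclude optional list (per dataset) of sample ids to drop before
#'   analysis (used by [posthoc_outlier_rerun()]).
#' @return an object of class `mtcn_mr`.
#' @export
run_mr <- function(datasets, penalty = c("both", "l1", "l2"),
                   selection = c("cross_validated", "fixed"), lambda = NULL,
                   m_imputations = 20, folds = 5, alpha_screen = NULL,
                   maf_min = 0.01, maxit = 5, seed = 1L,
                   prefilter_outliers = TRUE,
                   df_method = c("m-2", "barnard-rubin"), exclude = NULL) {
  penalty <- match.arg(penalty)
  selection <- match.arg(selection)
  df_method <- match.arg(df_method)
  if (m_imputations < 2L) stop("at least 2 imputations are required")
  if (!length(datasets)) stop("at least one dataset is required")
  kinds <- if (penalty == "both") c("l1", "l2") else penalty
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  dss <- lapply(seq_along(datasets), function(d)
    as_mr_dataset(datasets[[d]], names(datasets)[d]))
  prefilter_ids <- vector("list", length(dss))
  names(prefilter_ids) <- vapply(dss, `[[`, "", "name")
  for (d in seq_along(dss)) {
    ds <- dss[[d]]
    maf <- colMeans(ds$G) / 2
    keep_v <- pmin(maf, 1 - maf) >= maf_min
    ds$G <- ds$G[, keep_v, drop = FALSE]
    drop_ids <- character(0)
    if (prefilter_outliers) drop_ids <- mr_prefilter(ds)
    if (!is.null(exclude)) drop_ids <- union(drop_ids, exclude[[d]])
    prefilter_ids[[d]] <- drop_ids
    if (length(drop_ids)) {
      keep <- !(ds$sample_id %in% drop_ids)
      if (sum(keep) <= ncol(ds$W) + 5)
        stop("exclusions leave too few samples in dataset ", ds$name)
      ds$X <- ds$X[keep]; ds$Y <- ds$Y[keep]
      ds$W <- ds$W[keep, , drop = FALSE]
      ds$G <- ds$G[keep, , drop = FALSE]
      ds$sample_id <- ds$sample_id[keep]
    }
    dss[[d]] <- ds
  }
  penalties <- list()
  for (kind in kinds) {
    per_ds <- list()
    for (d in seq_along(dss)) {
      per_ds[[dss[[d]]$name]] <- run_mr_one(
        dss[[d]], kind, selection, lambda, m_imputations, folds,
        alpha_screen, maxit,
        seed = (seed + 7919L * d) %% .Machine$integer.max, df_method)
    }
    betas <- vapply(per_ds, function(r) r$pooled$beta, numeric(1))
    ses <- vapply(per_ds, function(r) r$pooled$se, numeric(1))
    penalties[[kind]] <- list(datasets = per_ds,
                              meta = meta_fixed_ivw(betas, ses))
  }
  structure(list(
    penalties = penalties, excluded = prefilter_ids,
    config = list(penalty = penalty, selection = selection, lambda = lambda,
                  m_imputations = m_imputations, folds = folds,
                  alpha_screen = alpha_screen, maf_min = maf_min,
                  maxit = maxit, seed = seed,
                  prefilter_outliers = prefilter_outliers,
                  df_method = df_method),
    call = match.call()
  ), class = "mtcn_mr")
}

#' Post hoc outlier exclusion and re-analysis
#'
#' Within every imputation of every dataset/penalty run, the samples with
#' standardized residual above 1 in the causality regression are ranked by
#' leverage and the top `top_k` recorded; any sample recorded at least once
#' is excluded, and the whole procedure is re-run on the reduced data. Both
#' results are returned side by side.
#'
#' @param fit an `mtcn_mr` object from [run_mr()].
#' @param datasets the dataset list originally passed to [run_mr()].
#' @param top_k samples recorded per imputation (default 10).
#' @return list(original, rerun, excluded) of class `mtcn_mr_posthoc`.
#' @export
posthoc_outlier_rerun <- function(fit, datasets, top_k = 10) {
  stopifnot(inherits(fit, "mtcn_mr"))
  ds_names <- names(fit$penalties[[1]]$datasets)
  excluded <- lapply(ds_names, function(nm) {
    ids <- character(0)
    for (kind in names(fit$penalties)) {
      for (dg in fit$penalties[[kind]]$datasets[[nm]]$diagnostics) {
        cand <- dg[abs(dg$std_residual) > 1, ]
        if (nrow(cand)) {
          cand <- cand[order(-cand$leverage), ]
          ids <- union(ids, utils::head(cand$sample_id, top_k))
        }
      }
    }
    ids
  })
  names(excluded) <- ds_names
  cfg <- fit$config
  rerun <- run_mr(datasets, penalty = cfg$penalty,
                  selection = cfg$selection, lambda = cfg$lambda,
                  m_imputations = cfg$m_imputations, folds = cfg$folds,
                  alpha_screen = cfg$alpha_screen, maf_min = cfg$maf_min,
                  maxit = cfg$maxit, seed = cfg$seed,
                  prefilter_outliers = cfg$prefilter_outliers,
                  df_method = cfg$df_method, exclude = excluded)
  structure(list(original = fit, rerun = rerun, excluded = excluded),
            class = "mtcn_mr_posthoc")
}

#' @export
print.mtcn_mr <- function(x, ...) {
  cat("Penalized-instrument Mendelian randomization (MT-CN -> insulin)\n")
  cat(sprintf("  %d dataset(s), %d imputations, %d folds, penalty: %s\n",
              length(x$penalties[[1]]$datasets), x$config$m_imputations,
              x$config$folds, x$config$penalty))
  for (kind in names(x$penalties)) {
    m <- x$penalties[[kind]]$meta
    cat(sprintf("  %s meta (IVW): beta = %.4f, se = %.4f, z = %.2f, p = %.3g\n",
                toupper(kind), m$beta, m$se, m$z, m$p))
  }
  invisible(x)
}

#' @export
summary.mtcn_mr <- function(object, ...) {
  rows <- do.call(rbind, lapply(names(object$penalties), function(kind) {
    pk <- object$penalties[[kind]]
    ds <- do.call(rbind, lapply(names(pk$datasets), function(nm) {
      p <- pk$datasets[[nm]]$pooled
      data.frame(penalty = kind, dataset = nm, beta = p$beta, se = p$se,
                 df = p$df, p = p$p, n = pk$datasets[[nm]]$n)
    }))
    meta <- data.frame(penalty = kind, dataset = "meta (IVW)",
                       beta = pk$meta$beta, se = pk$meta$se, df = NA,
                       p = pk$meta$p, n = sum(ds$n))
    rbind(ds, meta)
  }))
  rownames(rows) <- NULL
  structure(rows, class = c("summary.mtcn_mr", "data.frame"))
}

#' @export
print.summary.mtcn_mr <- function(x, ...) {
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
coef.mtcn_mr <- function(object, ...) {
  vapply(object$penalties, function(pk) pk$meta$beta, numeric(1))
}
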