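# Polygenic-score projection of the averaged instrument weights onto an
# independent cohort, and the cell-count / metabolic-trait association
# workflow with its outlier-removal stages and the neutrophil/platelet
# adjustment comparison.

#' Expected alternate allele dosage from genotype probabilities
#'
#' `DS = P(0/1) + 2 P(1/1)`, in \[0, 2\]. Accepts a length-3 triplet or an
#' n x 3 matrix of triplets; each triplet must sum to 1 (tolerance 1e-6).
#'
#' @param gp_triplet probabilities of (hom-ref, het, hom-alt).
#' @return numeric dosage(s).
#' @export
expected_dosage <- function(gp_triplet) {
  g <- if (is.null(dim(gp_triplet))) matrix(gp_triplet, ncol = 3)
       else as.matrix(gp_triplet)
  if (ncol(g) != 3L) stop("genotype probabilities must be triplets")
  if (any(abs(rowSums(g) - 1) > 1e-6))
    stop("genotype probability triplet does not sum to 1")
  as.numeric(g[, 2] + 2 * g[, 3])
}

#' Hard-call genotypes from expected dosages
#'
#' Thresholds 0.5 and 1.5; boundaries are assigned upward (0.5 -> 1,
#' 1.5 -> 2).
#'
#' @param DS dosages in \[0, 2\].
#' @return integer genotypes in \{0, 1, 2\} (matrix shape preserved).
#' @export
hard_call <- function(DS) {
  if (any(DS < 0 | DS > 2, na.rm = TRUE)) stop("dosage outside [0, 2]")
  out <- (DS >= 0.5) + (DS >= 1.5)
  storage.mode(out) <- "integer"
  out
}

#' Polygenic score from instrument weights
#'
#' Row-wise dot product of the hard-called genotype matrix with the averaged
#' instrument weights, matched by variant id. Unmatched ids are a hard
#' error; no variants are silently dropped.
#'
#' @param weights data.frame with columns `variant_id` and `weight`.
#' @param calls genotype matrix with variant ids as column names.
#' @return numeric score per sample.
#' @export
compute_prs <- function(weights, calls) {
  if (anyDuplicated(weights$variant_id)) stop("duplicate variant ids")
  missing_ids <- setdiff(weights$variant_id, colnames(calls))
  if (length(missing_ids))
    stop("variant ids absent from genotype matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  as.numeric(calls[, weights$variant_id, drop = FALSE] %*% weights$weight)
}

#' Transform cell-count and metabolic traits for association testing
#'
#' Lymphocyte count is reconstructed as leukocyte count times lymphocyte
#' fraction (percentages above 1 are auto-rescaled by 1/100); cell counts
#' are log-transformed and standardized to mean 0, SD 1 separately by sex;
#' metabolic traits are log-transformed. Values matching `na_codes`
#' (negative sentinel codes) become missing.
#'
#' @param tab data.frame of raw traits.
#' @param sex 0/1 vector.
#' @param cell_count_cols names of cell-count columns (after lymphocyte
#'   reconstruction).
#' @param metabolic_cols names of metabolic columns to log-transform only.
#' @param na_codes values treated as missing.
#' @return transformed data.frame (adds `lymphocyte` when leukocyte and
#'   lymphocyte_pct are present).
#' @export
prepare_traits <- function(tab, sex,
                           cell_count_cols = intersect(
                             c("leukocyte", "neutrophil", "lymphocyte",
                               "monocyte", "platelet"), names(tab)),
                           metabolic_cols = NULL,
                           na_codes = c(-1, -3)) {
  tab <- as.data.frame(tab)
  for (v in names(tab)) tab[[v]][tab[[v]] %in% na_codes] <- NA
  if (all(c("leukocyte", "lymphocyte_pct") %in% names(tab))) {
    frac <- tab$lymphocyte_pct
    if (any(frac > 1, na.rm = TRUE)) frac <- frac / 100
    tab$lymphocyte <- tab$leukocyte * frac
    cell_count_cols <- union(cell_count_cols, "lymphocyte")
  }
  for (v in cell_count_cols) {
    if (any(tab[[v]] <= 0, na.rm = TRUE))
      stop("nonpositive values submitted to log in ", v)
    x <- log(tab[[v]])
    for (s in unique(sex[!is.na(sex)])) {
      i <- which(sex == s & !is.na(x))
      x[i] <- (x[i] - mean(x[i])) / stats::sd(x[i])
    }
    tab[[v]] <- x
  }
  for (v in metabolic_cols) {
    if (any(tab[[v]] <= 0, na.rm = TRUE))
      stop("nonpositive values submitted to log in ", v)
    tab[[v]] <- log(tab[[v]])
  }
  tab
}

#' Iterated PCA outlier exclusion
#'
#' Up to `max_iter` rounds: center/scale the trait matrix, take principal
#' components, and exclude samples whose score on any component exceeds
#' `sd_threshold` standard deviations; stops early when a round excludes
#' nothing.
#'
#' @param mat numeric trait matrix (samples x traits).
#' @param sd_threshold exclusion threshold in component SDs (default 6).
#' @param max_iter maximum rounds (default 3).
#' @return integer row indices (into `mat`) of excluded samples.
#' @export
pca_outlier_iterate <- function(mat, sd_threshold = 6, max_iter = 3) {
  mat <- as.matrix(mat)
  active <- seq_len(nrow(mat))
  excluded <- integer(0)
  iter <- 0
  while (iter < max_iter && length(active) > ncol(mat) + 1) {
    iter <- iter + 1
    pc <- stats::prcomp(mat[active, , drop = FALSE],
                        center = TRUE, scale. = TRUE)
    keep_pc <- pc$sdev > 1e-10
    sc <- sweep(pc$x[, keep_pc, drop = FALSE], 2,
                pc$sdev[keep_pc], "/")
    bad <- which(apply(abs(sc), 1, max) > sd_threshold)
    if (!length(bad)) break
    excluded <- c(excluded, active[bad])
    active <- active[-bad]
  }
  if (!length(active)) stop("all samples excluded")
  sort(excluded)
}

#' Null-model residual/leverage outlier exclusion
#'
#' Fits the null covariate model and excludes samples with
#' `|standardized residual| > r_hi`, or leverage above `l_hi` together with
#' `|standardized residual| > r_mid`; refits and repeats up to `max_iter`
#' times.
#'
#' @param trait response vector.
#' @param design covariate model matrix (with intercept).
#' @param family `"linear"` or `"logistic"`.
#' @param r_hi,r_mid standardized-residual thresholds (defaults 6, 2).
#' @param l_hi leverage threshold; default `3 p / n`.
#' @param max_iter refit rounds (default 2).
#' @return integer indices (into `trait`) of excluded samples.
#' @export
nullmodel_outliers <- function(trait, design, family = c("linear", "logistic"),
                               r_hi = 6, r_mid = 2, l_hi = NULL,
                               max_iter = 2) {
  family <- match.arg(family)
  design <- as.matrix(design)
  if (is.null(l_hi)) l_hi <- 3 * ncol(design) / nrow(design)
  active <- seq_along(trait)
  excluded <- integer(0)
  for (it in seq_len(max_iter)) {
    fit <- if (family == "linear")
      fit_linear(trait[active], design[active, , drop = FALSE])
    else fit_logistic(trait[active], design[active, , drop = FALSE])
    sr <- abs(fit$std_residuals)
    bad <- which(sr > r_hi | (fit$leverage > l_hi & sr > r_mid))
    if (!length(bad)) break
    excluded <- c(excluded, active[bad])
    active <- active[-bad]
  }
  sort(excluded)
}

# Standard covariate design: Age + Age^2 + Sex + Age:Sex + Age^2:Sex + PCs.
replication_design <- function(age, sex, pcs = NULL) {
  age_c <- age - mean(age)
  d <- cbind(intercept = 1, age = age_c, age2 = age_c^2, sex = sex,
             age_sex = age_c * sex, age2_sex = age_c^2 * sex)
  if (!is.null(pcs) && NCOL(pcs) > 0) {
    pcs <- as.matrix(pcs)
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    d <- cbind(d, pcs)
  }
  d
}

#' Association between a trait and the MT-CN polygenic score
#'
#' Fits `trait ~ PRS + Age + Age^2 + Sex + Age:Sex + Age^2:Sex + PCs`
#' (logistic for binary traits) and reports the PRS coefficient row;
#' `extra_adjust` adds neutrophil and/or platelet counts to the design for
#' the cell-count-mediation comparison. Missing values are dropped
#' row-wise.
#'
#' @param trait response vector (transformed upstream).
#' @param prs polygenic score vector.
#' @param age,sex covariates.
#' @param pcs optional matrix of genotype principal components.
#' @param family `"linear"` or `"logistic"`.
#' @param extra_adjust optional named matrix/data.frame of cell counts to
#'   adjust for (e.g. neutrophil, platelet).
#' @return one-row data.frame: beta, se, statistic, p, family,
#'   adjusted_for_cell_counts, n.
#' @export
prs_association <- function(trait, prs, age, sex, pcs = NULL,
                            family = c("linear", "logistic"),
                            extra_adjust = NULL) {
  family <- match.arg(family)
  design <- cbind(prs = prs, replication_design(age, sex, pcs))
  adjusted <- !is.null(extra_adjust) && NCOL(extra_adjust) > 0
  if (adjusted) design <- cbind(design, as.matrix(extra_adjust))
  ok <- stats::complete.cases(design, trait)
  fit <- if (family == "linear") fit_linear(trait[ok], design[ok, ])
         else fit_logistic(trait[ok], design[ok, ])
  data.frame(beta = unname(fit$coefficients[1]),
             se = unname(fit$standard_errors[1]),
             statistic = unname(fit$statistics[1]),
             p = unname(fit$p_values[1]),
             family = family, adjusted_for_cell_counts = adjusted,
             n = sum(ok))
}
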