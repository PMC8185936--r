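# Mitochondrial genome copy number from sequencing coverage.
#
# Raw MT-CN is twice the ratio of mitochondrial depth to haploid autosomal
# coverage: the mean mitochondrial depth is the numerator for uniform
# whole-genome coverage, the maximum depth for hybrid-capture exome coverage
# (where probe-induced peaks make the mean a poor summary). The analysis
# phenotype is produced by batch-wise residualization on age, age^2 and sex
# followed by rank-based inverse normal transforms within and across batches.

#' Read a samtools-depth style table into a dense per-base depth vector
#'
#' Input columns are contig, 1-based position, depth. Positions absent from
#' the file are depth 0 (genome-wide per-base coverage semantics). Positions
#' beyond `contig_length` are an error.
#'
#' @param path TSV file (no header).
#' @param contig_filter keep only rows for this contig (`NULL` keeps all).
#' @param contig_length length of the dense output vector; defaults to the
#'   largest position seen.
#' @return integer-ish numeric vector of length `contig_length`.
#' @export
read_depth_table <- function(path, contig_filter = NULL,
                             contig_length = NULL) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("contig", "pos", "depth"),
                      stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", basename(path), ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.null(contig_filter)) tab <- tab[tab$contig == contig_filter, ]
  if (!is.numeric(tab$depth) || !is.numeric(tab$pos))
    stop("depth table has non-numeric position or depth")
  if (is.null(contig_length)) contig_length <- max(tab$pos, 0)
  if (nrow(tab) > 0 && max(tab$pos) > contig_length)
    stop("positions beyond stated contig length")
  out <- numeric(contig_length)
  out[tab$pos] <- tab$depth
  out
}

#' Summarize a depth vector for MT-CN estimation
#'
#' @param depth dense per-base depth vector.
#' @param haploid_autosomal_coverage per-sample haploid autosomal coverage.
#' @param sample_id identifier.
#' @return one-row data.frame: sample_id, mean_mt_depth, max_mt_depth,
#'   haploid_autosomal_coverage.
#' @export
coverage_summary <- function(depth, haploid_autosomal_coverage,
                             sample_id = NA_character_) {
  data.frame(sample_id = sample_id,
             mean_mt_depth = mean(depth),
             max_mt_depth = max(depth),
             haploid_autosomal_coverage = haploid_autosomal_coverage)
}

#' WGS MT-CN estimator: mean mitochondrial depth
#'
#' `2 * mean_mt_depth / haploid_autosomal_coverage` -- twice the ratio of
#' mean mitochondrial to haploid autosomal coverage, so a diploid-equivalent
#' contig yields 2.
#'
#' @param cs data.frame with columns `mean_mt_depth` and
#'   `haploid_autosomal_coverage` (one row per sample).
#' @return numeric vector of raw MT-CN values.
#' @export
mtcn_wgs <- function(cs) {
  if (any(cs$haploid_autosomal_coverage <= 0))
    stop("haploid autosomal coverage must be positive")
  2 * cs$mean_mt_depth / cs$haploid_autosomal_coverage
}

#' WES MT-CN estimator: maximum mitochondrial depth
#'
#' `2 * max_mt_depth / haploid_autosomal_coverage`. With hybrid-capture
#' probes the mitochondrial coverage is peaked, and the maximum tracks copy
#' number more faithfully than the mean; under uniform coverage it reduces
#' to the mean-depth estimator up to Poisson noise.
#'
#' @param cs data.frame with columns `max_mt_depth` and
#'   `haploid_autosomal_coverage`.
#' @return numeric vector of raw MT-CN values.
#' @export
mtcn_wes <- function(cs) {
  if (any(cs$haploid_autosomal_coverage <= 0))
    stop("haploid autosomal coverage must be positive")
  2 * cs$max_mt_depth / cs$haploid_autosomal_coverage
}

#' Batch-wise normalization of raw MT-CN to the analysis phenotype
#'
#' Within each batch the raw values are residualized by OLS on age, age^2
#' and sex (sex only when the batch contains both sexes, avoiding
#' rank-deficient designs in single-sex batches), then inverse rank normal
#' transformed; the per-batch results are pooled and transformed once more.
#' The output is therefore invariant to any strictly monotone within-batch
#' transformation of the raw values, including additive batch offsets.
#'
#' @param records data.frame with columns `sample_id`, `raw_mtcn`, `batch`,
#'   `age` and optionally `sex` (0/1).
#' @return `records` with a `normalized_mtcn` column appended.
#' @export
normalize_mtcn <- function(records) {
  if (any(records$raw_mtcn <= 0)) stop("raw_mtcn must be positive")
  records$normalized_mtcn <- NA_real_
  for (b in unique(records$batch)) {
    idx <- which(records$batch == b)
    sub <- records[idx, ]
    design <- cbind(intercept = 1, age = sub$age, age2 = sub$age^2)
    if (!is.null(sub$sex) && length(unique(sub$sex)) > 1L)
      design <- cbind(design, sex = sub$sex)
    if (length(idx) <= ncol(design))
      stop("batch ", b, " has too few samples for its covariates")
    res <- fit_linear(sub$raw_mtcn, design)$residuals
    records$normalized_mtcn[idx] <- inverse_rank_normal(res)
  }
  records$normalized_mtcn <- inverse_rank_normal(records$normalized_mtcn)
  records
}

#' Concordance between two MT-CN estimators
#'
#' Squared Pearson correlation between paired estimates.
#'
#' @param wgs_values,wes_values paired numeric vectors.
#' @return R^2 scalar.
#' @export
estimator_concordance <- function(wgs_values, wes_values) {
  if (length(wgs_values) != length(wes_values))
    stop("estimates must be paired")
  if (stats::sd(wgs_values) == 0 || stats::sd(wes_values) == 0)
    stop("zero variance in one of the estimators")
  stats::cor(wgs_values, wes_values)^2
}
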