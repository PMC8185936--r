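# Plain-text serialization of synthetic cohorts: dosage/GP TSVs (lossless
# channel, 17 significant digits), a minimal VCF 4.2 with GT:GP:DS (printed
# precision), phenotype/covariate TSVs with "NA" missing code, YAML config
# and JSON truth record.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_precise <- function(df, path) {
  df2 <- as.data.frame(lapply(df, function(col)
    if (is.double(col)) fmt_num(col) else col), check.names = FALSE,
    stringsAsFactors = FALSE)
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_checked <- function(path) {
  tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", basename(path), ": ",
                             conditionMessage(e), call. = FALSE)
  )
}

#' Write a synthetic cohort to plain-text fixture files
#'
#' Produces `dosages.tsv`, `gp.tsv`, `genotypes.vcf` (GT:GP:DS),
#' `phenotypes.tsv`, `missing_mask.tsv`, `latent.tsv`, `config.yaml` and
#' `truth.json` under `dir`. The TSV files round-trip all matrices to better
#' than 1e-12; the VCF carries its printed 6-decimal precision.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- cohort$sample_id
  dos <- data.frame(sample_id = ids, cohort$dosages, check.names = FALSE)
  write_tsv_precise(dos, file.path(dir, "dosages.tsv"))

  gp <- cohort$gp
  gp_flat <- do.call(cbind, lapply(seq_len(dim(gp)[2]), function(j) {
    m <- gp[, j, ]
    colnames(m) <- paste0(dimnames(gp)[[2]][j], "_", c("AA", "AB", "BB"))
    m
  }))
  write_tsv_precise(data.frame(sample_id = ids, gp_flat, check.names = FALSE),
                    file.path(dir, "gp.tsv"))

  write_cohort_vcf(cohort, file.path(dir, "genotypes.vcf"))

  phen <- data.frame(sample_id = ids, age = cohort$age, sex = cohort$sex,
                     batch = cohort$batch, X = cohort$X, Y = cohort$Y,
                     mtcn_raw = cohort$mtcn_raw, cohort$W,
                     cohort$cell_counts, check.names = FALSE)
  write_tsv_precise(phen, file.path(dir, "phenotypes.tsv"))
  write_tsv_precise(data.frame(sample_id = ids, cohort$missing_mask,
                               check.names = FALSE),
                    file.path(dir, "missing_mask.tsv"))
  write_tsv_precise(data.frame(sample_id = ids, U = cohort$U, C = cohort$C,
                               check.names = FALSE),
                    file.path(dir, "latent.tsv"))
  cfg <- cohort$config
  cfg_out <- lapply(unclass(cfg), function(x)
    if (is.numeric(x)) as.numeric(x) else x)
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a synthetic cohort back from fixture files
#'
#' Inverse of [write_fixtures()] (TSV channel; the VCF is a parallel export,
#' see [read_vcf_dosages()]). Malformed files raise a parse error naming the
#' file.
#'
#' @param dir directory written by [write_fixtures()].
#' @return a `synthetic_cohort`-shaped list.
#' @export
read_fixtures <- function(dir) {
  dos_df <- read_tsv_checked(file.path(dir, "dosages.tsv"))
  ids <- dos_df$sample_id
  dos <- as.matrix(dos_df[, -1, drop = FALSE])
  rownames(dos) <- ids
  gp_df <- read_tsv_checked(file.path(dir, "gp.tsv"))
  gp_mat <- as.matrix(gp_df[, -1, drop = FALSE])
  m <- ncol(gp_mat) / 3L
  if (m != round(m)) stop("failed to parse gp.tsv: column count not 3 per variant")
  gp <- array(0, dim = c(nrow(gp_mat), m, 3),
              dimnames = list(ids, colnames(dos), c("AA", "AB", "BB")))
  for (j in seq_len(m)) gp[, j, ] <- gp_mat[, (3 * j - 2):(3 * j)]
  phen <- read_tsv_checked(file.path(dir, "phenotypes.tsv"))
  mask <- read_tsv_checked(file.path(dir, "missing_mask.tsv"))
  latent <- read_tsv_checked(file.path(dir, "latent.tsv"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  wcols <- setdiff(names(phen), c("sample_id", "age", "sex", "batch", "X",
                                  "Y", "mtcn_raw", "leukocyte", "neutrophil",
                                  "lymphocyte_pct", "monocyte", "platelet"))
  structure(list(
    sample_id = ids, dosages = dos, gp = gp,
    W = as.matrix(phen[, wcols, drop = FALSE]),
    U = latent$U, C = latent$C, X = phen$X, Y = phen$Y,
    age = phen$age, sex = phen$sex, batch = phen$batch,
    cell_counts = phen[, c("leukocyte", "neutrophil", "lymphocyte_pct",
                           "monocyte", "platelet")],
    mtcn_raw = phen$mtcn_raw,
    missing_mask = mask[, -1, drop = FALSE],
    truth = truth, config = cfg
  ), class = "synthetic_cohort")
}

#' Write cohort genotypes as a minimal VCF 4.2
#'
#' One biallelic record per variant with FORMAT `GT:GP:DS`; the GT hard call
#' uses the 0.5/1.5 dosage thresholds, GP and DS carry six decimals.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  dos <- cohort$dosages
  gp <- cohort$gp
  n <- nrow(dos); m <- ncol(dos)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probabilities\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t")
  )
  gt_codes <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(m), function(j) {
    calls <- hard_call(dos[, j])
    field <- sprintf("%s:%.6f,%.6f,%.6f:%.6f",
                     gt_codes[calls + 1L],
                     gp[, j, 1], gp[, j, 2], gp[, j, 3], dos[, j])
    paste(c("1", as.character(j * 1000L), colnames(dos)[j], "A", "G", ".",
            "PASS", ".", "GT:GP:DS", field), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a dosage matrix from a VCF with a DS FORMAT field
#'
#' Uses vcfR to parse the file; returns samples x variants expected alternate
#' allele dosages.
#'
#' @param path VCF file (plain text or gzipped).
#' @return numeric matrix, rows = samples, columns = variant IDs.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosages() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  t(ds)
}

#' Write per-sample depth profiles as samtools-depth TSVs
#'
#' One file per sample (`<id>.depth.tsv`) with columns contig, 1-based
#' position, depth; zero-depth positions are omitted, matching the
#' samtools-depth default.
#'
#' @param profiles L x n integer matrix of per-base depths.
#' @param ids sample identifiers (length n).
#' @param dir output directory.
#' @param contig contig name to write.
#' @return character vector of file paths, invisibly.
#' @export
write_depth_tsvs <- function(profiles, ids, dir, contig = "chrM") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(ids), function(i) {
    d <- profiles[, i]
    keep <- d > 0
    p <- file.path(dir, paste0(ids[i], ".depth.tsv"))
    utils::write.table(
      data.frame(contig, which(keep), d[keep]),
      p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
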