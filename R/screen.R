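# Phenome-wide screen of a score against a curated phenotype table, with
# dual raw/normalized handling of continuous traits and BH+Storey FDR
# control over the categorical + one-continuous-form family.

#' Curate a phenotype table for the phenome screen
#'
#' Continuous variables are emitted twice, raw and inverse rank normalized;
#' binary variables are kept as is; unordered categorical variables are
#' expanded to one-vs-rest binary indicators for logistic testing;
#' sex-specific (or declared nearly sex-specific) categorical variables and
#' constant columns are excluded with a reason.
#'
#' @param table data.frame of phenotype columns.
#' @param metadata data.frame with columns `column`,
#'   `type` (`"continuous"`, `"binary"`, `"categorical"`) and `sex_specific`
#'   (logical).
#' @return list of curated-variable lists (name, kind, values, source,
#'   excluded, reason).
#' @export
curate_phenotypes <- function(table, metadata) {
  out <- list()
  for (i in seq_len(nrow(metadata))) {
    col <- metadata$column[i]
    type <- metadata$type[i]
    if (!col %in% names(table)) stop("metadata names unknown column ", col)
    v <- table[[col]]
    add <- function(entry) out[[length(out) + 1L]] <<- entry
    if (!type %in% c("continuous", "binary", "categorical"))
      stop("undeclared column type for ", col, ": ", type)
    if (length(unique(v[!is.na(v)])) < 2L) {
      add(list(name = col, kind = type, values = NULL, source = col,
               excluded = TRUE, reason = "constant"))
      next
    }
    if (type == "categorical" && isTRUE(metadata$sex_specific[i])) {
      add(list(name = col, kind = "categorical_unordered", values = NULL,
               source = col, excluded = TRUE, reason = "sex-specific"))
      next
    }
    if (type == "continuous") {
      add(list(name = paste0(col, ".raw"), kind = "continuous_raw",
               values = as.numeric(v), source = col, excluded = FALSE,
               reason = NA_character_))
      add(list(name = paste0(col, ".irn"), kind = "continuous_irn",
               values = inverse_rank_normal(as.numeric(v)), source = col,
               excluded = FALSE, reason = NA_character_))
    } else if (type == "binary") {
      add(list(name = col, kind = "binary", values = as.numeric(v),
               source = col, excluded = FALSE, reason = NA_character_))
    } else {
      lev <- sort(unique(v[!is.na(v)]))
      for (l in lev)
        add(list(name = paste0(col, ".", l), kind = "categorical_unordered",
                 values = as.numeric(v == l), source = col,
                 excluded = FALSE, reason = NA_character_))
    }
  }
  out
}

#' Phenome-wide screen of a score against curated phenotypes
#'
#' Continuous forms are tested with linear regression, binary and
#' categorical indicators with logistic regression, all with the standard
#' covariate design (age, age-squared, sex, their interactions, PCs) and
#' optionally neutrophil and platelet counts. q-values are computed by
#' [qvalues_bh_storey()] over two families: the primary family joins the
#' categorical/binary tests with the inverse-rank-normalized continuous
#' forms, the secondary family joins them with the raw forms.
#'
#' @param score numeric score (e.g. the MT-CN PRS).
#' @param curated output of [curate_phenotypes()].
#' @param age,sex,pcs covariates as in [prs_association()].
#' @param cell_counts optional matrix of neutrophil/platelet counts.
#' @param adjust_cell_counts add `cell_counts` to the design.
#' @return data.frame of screen rows: name, kind, family membership, beta,
#'   se, p, q_primary, q_secondary, n.
#' @export
run_screen <- function(score, curated, age, sex, pcs = NULL,
                       cell_counts = NULL, adjust_cell_counts = FALSE) {
  extra <- if (adjust_cell_counts) cell_counts else NULL
  active <- Filter(function(cv) !cv$excluded, curated)
  if (!length(active)) stop("no testable variables after curation")
  # shared covariate design: linear fits with complete data reduce exactly to
  # the partialled (Frisch-Waugh) regression on the residualized score
  D <- replication_design(age, sex, pcs)
  if (!is.null(extra)) D <- cbind(D, as.matrix(extra))
  fast_ok <- !anyNA(D) && !anyNA(score)
  if (fast_ok) {
    qrD <- qr(D)
    rs <- qr.resid(qrD, score)
    rs2 <- sum(rs^2)
    df_fast <- nrow(D) - ncol(D) - 1
  }
  rows <- do.call(rbind, lapply(active, function(cv) {
    fam <- if (cv$kind %in% c("continuous_raw", "continuous_irn"))
      "linear" else "logistic"
    if (fam == "linear" && fast_ok && !anyNA(cv$values)) {
      rt <- qr.resid(qrD, cv$values)
      beta <- sum(rs * rt) / rs2
      se <- sqrt(sum((rt - beta * rs)^2) / df_fast / rs2)
      tv <- beta / se
      res <- data.frame(beta = beta, se = se, statistic = tv,
                        p = 2 * stats::pt(-abs(tv), df_fast), n = nrow(D))
    } else {
      res <- prs_association(cv$values, score, age, sex, pcs = pcs,
                             family = fam, extra_adjust = extra)
    }
    data.frame(name = cv$name, kind = cv$kind, beta = res$beta, se = res$se,
               statistic = res$statistic, p = res$p, n = res$n)
  }))
  categ <- rows$kind %in% c("binary", "categorical_unordered")
  primary <- categ | rows$kind == "continuous_irn"
  secondary <- categ | rows$kind == "continuous_raw"
  if (!any(primary) || !any(secondary))
    stop("a q-value family has zero tests")
  rows$q_primary <- rows$q_secondary <- NA_real_
  rows$q_primary[primary] <- qvalues_bh_storey(rows$p[primary])$q_values
  rows$q_secondary[secondary] <- qvalues_bh_storey(rows$p[secondary])$q_values
  rows
}
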