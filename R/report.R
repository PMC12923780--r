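#' Group-comparison report for a cohort
#'
#' Reproduces the two-table analysis layout of the reference study on a
#' cohort data frame: demographic/clinical comparisons by independent
#' t-tests (continuous) and chi-square (categorical) with Cohen's d, then
#' ANCOVA comparisons of the twelve ROI diffusivity components and the ALPS
#' index adjusted for the stated covariates, with f = |d|/2 effect sizes and
#' Bonferroni correction over that family, and finally Pearson and partial
#' correlations between ALPS and sleep/clinical measures within the T2DM
#' group.
#'
#' @param cohort Data frame from [sample_cohort()] (or the same schema for
#'   real data), with groups labelled `T2DM` and `control`.
#' @param alps Optional data frame `subject_id`, `alps` of pipeline-measured
#'   ALPS values to join; otherwise the column `alps` or `alps_target` in
#'   `cohort` is analysed.
#' @param covars Covariate column names for the ANCOVA (after binary coding;
#'   `sex` is used as `sex_male`). Default age, sex, BMI.
#' @param extended Add the binary-coded MoCA, ESS and OSA covariates to the
#'   ANCOVA set.
#' @param bonferroni_m Bonferroni family size for the diffusivity/ALPS
#'   comparisons; defaults to the 13 rows tested.
#' @param welch Use Welch rather than Student t-tests for the clinical table.
#' @return An object of class `alps_report`: list of data frames `table1`,
#'   `table2`, `correlations`.
#' @export
run_table1_table2 <- function(cohort, alps = NULL,
                              covars = c("age", "sex", "bmi"),
                              extended = FALSE,
                              bonferroni_m = NULL, welch = FALSE) {
  cohort <- binarize_covariates(cohort)
  if (!is.null(alps)) {
    cohort$alps <- alps$alps[match(cohort$subject_id, alps$subject_id)]
  }
  if (!"alps" %in% names(cohort)) {
    if (!"alps_target" %in% names(cohort)) {
      stopf("cohort has neither an 'alps' nor an 'alps_target' column")
    }
    cohort$alps <- cohort$alps_target
  }
  if (!all(c("T2DM", "control") %in% cohort$group)) {
    stopf("cohort must contain groups 'T2DM' and 'control'")
  }
  g1 <- cohort[cohort$group == "T2DM", , drop = FALSE]
  g2 <- cohort[cohort$group == "control", , drop = FALSE]

  comparison_row <- function(variable, model, p, d = NA_real_,
                             f = NA_real_, covariates = "") {
    x <- g1[[variable]]; y <- g2[[variable]]
    data.frame(
      variable = variable, model = model,
      mean_t2dm = mean(x, na.rm = TRUE), sd_t2dm = stats::sd(x, na.rm = TRUE),
      mean_ctrl = mean(y, na.rm = TRUE), sd_ctrl = stats::sd(y, na.rm = TRUE),
      p = p, p_bonf = NA_real_, d = d, f = f,
      covariates = covariates, stringsAsFactors = FALSE
    )
  }

  # -- Table 1: demographics and clinical scores (pairwise deletion) -------
  t1_vars <- intersect(c("age", "bmi", "hba1c", "psqi", "ess", "moca"),
                       names(cohort))
  table1 <- do.call(rbind, lapply(t1_vars, function(v) {
    x <- g1[[v]]; y <- g2[[v]]
    ht <- independent_t_test(x, y, equal_variance = !welch)
    d <- cohens_d(mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE),
                  mean(y, na.rm = TRUE), stats::sd(y, na.rm = TRUE))
    comparison_row(v, "ttest", ht$p, d = d)
  }))
  for (v in intersect(c("sex", "osa"), names(cohort))) {
    tab <- table(cohort$group, cohort[[v]])
    row <- tryCatch({
      ht <- chi_square_test(tab)
      data.frame(
        variable = v, model = "chisq",
        mean_t2dm = NA_real_, sd_t2dm = NA_real_,
        mean_ctrl = NA_real_, sd_ctrl = NA_real_,
        p = ht$p, p_bonf = NA_real_, d = NA_real_, f = NA_real_,
        covariates = "", stringsAsFactors = FALSE
      )
    }, error = function(e) NULL)  # zero marginal (e.g. OSA absent) -> skip
    if (!is.null(row)) table1 <- rbind(table1, row)
  }

  # -- Table 2: diffusivities + ALPS by ANCOVA -----------------------------
  covar_cols <- ifelse(covars == "sex", "sex_male", covars)
  if (extended) {
    covar_cols <- unique(c(covar_cols, "moca_low", "ess_high", "osa"))
  }
  covar_cols <- intersect(covar_cols, names(cohort))
  diff_vars <- grep("^d[xyz]{2}_(pro|asc)$", names(cohort), value = TRUE)
  t2_vars <- c(diff_vars, "alps")
  table2 <- do.call(rbind, lapply(t2_vars, function(v) {
    cc <- if (length(covar_cols)) cohort[, covar_cols, drop = FALSE] else NULL
    ht <- ancova_group_test(cohort[[v]], cohort$group, cc)
    x <- g1[[v]]; y <- g2[[v]]
    d <- cohens_d(mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE),
                  mean(y, na.rm = TRUE), stats::sd(y, na.rm = TRUE))
    comparison_row(v, "ancova", ht$p, d = d, f = cohens_f(d),
                   covariates = paste(covar_cols, collapse = "+"))
  }))
  m <- if (is.null(bonferroni_m)) nrow(table2) else bonferroni_m
  table2$p_bonf <- bonferroni_adjust(table2$p, m = m)

  # -- Correlations: ALPS vs sleep/clinical measures within T2DM -----------
  corr_vars <- intersect(c("psqi", "ess", "duration", "hba1c"), names(g1))
  part_cols <- intersect(c("age", "sex_male", "bmi"), names(g1))
  correlations <- do.call(rbind, lapply(corr_vars, function(v) {
    # too-small or degenerate samples yield NA rows rather than aborting
    pc <- tryCatch(pearson_correlation(g1$alps, g1[[v]]),
                   error = function(e) list(r = NA_real_, p = NA_real_, n = NA))
    pr <- tryCatch(
      partial_correlation(g1$alps, g1[[v]], g1[, part_cols, drop = FALSE]),
      error = function(e) list(r = NA_real_, p = NA_real_, n = NA)
    )
    data.frame(
      variable = v, r = pc$r, p = pc$p, n = pc$n,
      partial_r = pr$r, partial_p = pr$p, partial_n = pr$n,
      covariates = paste(part_cols, collapse = "+"),
      stringsAsFactors = FALSE
    )
  }))

  structure(
    list(table1 = table1, table2 = table2, correlations = correlations),
    class = "alps_report"
  )
}

#' @export
print.alps_report <- function(x, ...) {
  cat("== Clinical comparisons (t / chi-square) ==\n")
  t1 <- x$table1
  t1[, c("mean_t2dm", "sd_t2dm", "mean_ctrl", "sd_ctrl", "d")] <-
    round(t1[, c("mean_t2dm", "sd_t2dm", "mean_ctrl", "sd_ctrl", "d")], 2)
  t1$p <- signif(t1$p, 3)
  print(t1[, c("variable", "model", "mean_t2dm", "sd_t2dm",
               "mean_ctrl", "sd_ctrl", "p", "d")], row.names = FALSE)
  cat("\n== Diffusivity / ALPS comparisons (ANCOVA) ==\n")
  t2 <- x$table2
  t2[, c("mean_t2dm", "sd_t2dm", "mean_ctrl", "sd_ctrl", "d", "f")] <-
    round(t2[, c("mean_t2dm", "sd_t2dm", "mean_ctrl", "sd_ctrl", "d", "f")], 2)
  t2$p <- signif(t2$p, 3); t2$p_bonf <- signif(t2$p_bonf, 3)
  print(t2[, c("variable", "mean_t2dm", "sd_t2dm", "mean_ctrl", "sd_ctrl",
               "p", "p_bonf", "f")], row.names = FALSE)
  cat("\n== ALPS correlations within T2DM ==\n")
  cr <- x$correlations
  cr[, c("r", "partial_r")] <- round(cr[, c("r", "partial_r")], 2)
  cr$p <- signif(cr$p, 3); cr$partial_p <- signif(cr$partial_p, 3)
  print(cr, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to disk
#'
#' CSV output holds the comparison rows (clinical table followed by the
#' diffusivity/ALPS table) with the fixed column order
#' `variable,model,mean_t2dm,sd_t2dm,mean_ctrl,sd_ctrl,p,p_bonf,d,f,covariates`;
#' JSON output serialises the full report including the correlation block.
#' An empty report writes a valid header-only file.
#'
#' @param report An `alps_report` (or a data frame of comparison rows).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("variable", "model", "mean_t2dm", "sd_t2dm", "mean_ctrl",
            "sd_ctrl", "p", "p_bonf", "d", "f", "covariates")
  if (inherits(report, "alps_report")) {
    rows <- rbind(report$table1, report$table2)
  } else {
    rows <- as.data.frame(report)
    for (cl in setdiff(cols, names(rows))) rows[[cl]] <- NA
  }
  rows <- rows[, cols, drop = FALSE]
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    payload <- if (inherits(report, "alps_report")) {
      list(comparisons = rows, correlations = report$correlations)
    } else {
      list(comparisons = rows)
    }
    jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a comparison report written as CSV
#'
#' @param path CSV path from [write_report()].
#' @return Data frame of comparison rows.
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
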