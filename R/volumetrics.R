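# Subject-level tables are wide data frames: one row per subject, columns
# subject_id, sex (factor, levels F then M so positive betas are male-biased),
# age, ttv, a QC covariate (euler for humans, strain for mice), optional
# batch and family_id, and one "vol_<region>" column per region.

#' Run the seeded expression with an isolated RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @keywords internal
#' @noRd
region_columns <- function(table) {
  grep("^vol_", names(table), value = TRUE)
}

#' Exclude subjects failing surface-reconstruction quality control
#'
#' Drops subjects whose Euler number (a mesh-topology quality index from
#' cortical reconstruction; more negative = worse) falls below a threshold.
#' The conventional cutoff of -200 follows published quality-control
#' practice for large structural MRI cohorts.
#'
#' @param table Subject table with a numeric Euler column.
#' @param euler_threshold Exclusion threshold; subjects with Euler strictly
#'   below it are removed. Default -200.
#' @param euler_col Name of the Euler column.
#' @return The filtered table, with attribute `n_excluded`.
#' @export
apply_qc_exclusions <- function(table, euler_threshold = -200,
                                euler_col = "euler") {
  if (!euler_col %in% names(table))
    stop("missing Euler column '", euler_col, "'", call. = FALSE)
  keep <- table[[euler_col]] >= euler_threshold
  keep[is.na(keep)] <- FALSE
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  if (sum(!keep) > 0)
    message(sum(!keep), " subject(s) excluded at Euler threshold ",
            euler_threshold)
  out
}

#' Z-score a response vector
#'
#' Centers to mean 0 and scales to sample SD 1. Constant input is an error
#' (a silent vector of zeros would poison downstream effect sizes).
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return The standardized vector.
#' @export
zscore_response <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values to z-score", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: constant values cannot be z-scored",
         call. = FALSE)
  (values - mean(values)) / s
}

#' @keywords internal
#' @noRd
build_design <- function(table, response, include_ttv, sex_col, age_col,
                         ttv_col, qc_col, zscore_ttv) {
  df <- data.frame(y = zscore_response(table[[response]]))
  sex <- table[[sex_col]]
  if (!is.factor(sex)) sex <- factor(sex, levels = c("F", "M"))
  if (any(is.na(sex))) stop("missing sex values", call. = FALSE)
  df$sex <- sex
  if (!is.null(age_col) && age_col %in% names(table))
    df$age_c <- table[[age_col]] - mean(table[[age_col]])
  if (include_ttv && response != ttv_col) {
    ttv <- table[[ttv_col]]
    df$ttv <- if (zscore_ttv) zscore_response(ttv) else ttv
  }
  if (!is.null(qc_col)) {
    if (!qc_col %in% names(table))
      stop("missing QC covariate column '", qc_col, "'", call. = FALSE)
    qc <- table[[qc_col]]
    if (is.character(qc)) qc <- factor(qc)
    if (is.factor(qc) && nlevels(droplevels(qc)) < 2L)
      qc <- NULL  # single strain carries no information
    if (!is.null(qc)) df$qc <- if (is.factor(qc)) droplevels(qc) else qc
  }
  df
}

#' Standardized sex effect on one volume
#'
#' Fits the ordinary least-squares model
#' `z(volume) ~ sex + centered age + TTV + QC covariate` and returns the sex
#' coefficient. Because the response is z-scored, the sex coefficient is a
#' standardized effect size: positive values are male-biased (female is the
#' reference level). The QC covariate is the Euler number for human-style
#' tables or background strain (a factor, expanded by treatment coding) for
#' mouse-style tables; both enter through the same code path.
#'
#' @param table Subject table (see [simulate_cohort()] for the layout).
#' @param response Column to model, e.g. `"vol_Hippocampus (left)"` or
#'   `"ttv"`. When the response is the TTV column itself, TTV is
#'   automatically excluded from the covariates.
#' @param include_ttv Covary for total tissue volume? Default `TRUE`.
#' @param sex_col,age_col,ttv_col,qc_col Column names; `qc_col = NULL` omits
#'   the QC covariate, and `age_col` absent from the table is skipped.
#' @param zscore_ttv Standardize the TTV covariate before entry? The sex
#'   effect estimate is invariant to this; exposed for sensitivity checks.
#' @return A list of class `sex_effect_fit`: `region`, `beta_sex`, `se`,
#'   `t`, `p`, `n`, `df`, and the full `coefficients` table.
#' @export
fit_sex_effect <- function(table, response, include_ttv = TRUE,
                           sex_col = "sex", age_col = "age",
                           ttv_col = "ttv", qc_col = NULL,
                           zscore_ttv = FALSE) {
  if (!response %in% names(table))
    stop("response column '", response, "' not found", call. = FALSE)
  df <- build_design(table, response, include_ttv, sex_col, age_col,
                     ttv_col, qc_col, zscore_ttv)
  if (nlevels(droplevels(df$sex)) < 2L)
    stop("both sexes must be present", call. = FALSE)
  fit <- tryCatch(
    stats::lm(y ~ ., data = df, singular.ok = FALSE),
    error = function(e) stop("singular design for '", response, "': ",
                             conditionMessage(e), call. = FALSE))
  if (fit$df.residual < 1L)
    stop("insufficient data: no residual degrees of freedom", call. = FALSE)
  cf <- stats::coef(summary(fit))
  row <- grep("^sex", rownames(cf))
  structure(
    list(region = response,
         beta_sex = cf[row, "Estimate"],
         se = cf[row, "Std. Error"],
         t = cf[row, "t value"],
         p = cf[row, "Pr(>|t|)"],
         n = nrow(df),
         df = fit$df.residual,
         coefficients = cf),
    class = "sex_effect_fit")
}

#' @export
print.sex_effect_fit <- function(x, ...) {
  cat(sprintf("Standardized sex effect on %s\n", x$region))
  cat(sprintf("  beta = %.4f (SE %.4f), t(%d) = %.3f, p = %.4g, n = %d\n",
              x$beta_sex, x$se, x$df, x$t, x$p, x$n))
  invisible(x)
}

#' @export
coef.sex_effect_fit <- function(object, ...) {
  c(beta_sex = object$beta_sex)
}

#' Standardized sex effects across all regions, with FDR control
#'
#' Applies [fit_sex_effect()] to every `vol_` column (or a supplied region
#' set) and adjusts the two-sided p-values with the Benjamini-Hochberg
#' step-up procedure at level `q_level`.
#'
#' @inheritParams fit_sex_effect
#' @param regions Character vector of response columns; default all
#'   `vol_`-prefixed columns.
#' @param q_level Expected proportion of false positives, default 0.05.
#' @param ... Passed to [fit_sex_effect()].
#' @return A data frame of class `sex_effects` with columns `region`
#'   (the `vol_` prefix stripped), `beta_sex`, `se`, `t`, `p`, `q`,
#'   `significant`, `n`.
#' @export
fit_sex_effects <- function(table, regions = NULL, q_level = 0.05, ...) {
  if (is.null(regions)) regions <- region_columns(table)
  if (length(regions) == 0L)
    stop("no region columns found (expected 'vol_' prefix)", call. = FALSE)
  fits <- lapply(regions, function(rg) fit_sex_effect(table, rg, ...))
  out <- data.frame(
    region = sub("^vol_", "", regions),
    beta_sex = vapply(fits, `[[`, numeric(1), "beta_sex"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    t = vapply(fits, `[[`, numeric(1), "t"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    n = vapply(fits, `[[`, integer(1), "n"),
    stringsAsFactors = FALSE)
  adj <- fdr_adjust(out$p, q_level = q_level)
  out$q <- adj$q
  out$significant <- adj$significant
  attr(out, "q_level") <- q_level
  class(out) <- c("sex_effects", "data.frame")
  out
}

#' @export
print.sex_effects <- function(x, ...) {
  cat(sprintf("Standardized sex effects for %d regions (q level %.2f)\n",
              nrow(x), attr(x, "q_level")))
  cat(sprintf("  significant: %d (%.1f%%)\n", sum(x$significant),
              100 * mean(x$significant)))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("  ... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' @export
coef.sex_effects <- function(object, ...) {
  stats::setNames(object$beta_sex, object$region)
}

#' @export
summary.sex_effects <- function(object, ...) {
  summarize_sex_bias(object)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values with significance flags at level `q_level`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param q_level Expected proportion of false positives, default 0.05.
#' @return A list with `q` (adjusted values) and `significant`
#'   (`q <= q_level`).
#' @export
fdr_adjust <- function(pvalues, q_level = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, significant = q <= q_level)
}

#' Residualize region volumes on nuisance covariates
#'
#' OLS residuals of each region volume on the given covariate columns (an
#' intercept is always included; sex must not be among them so that
#' sex-linked variance survives for variance testing).
#'
#' @param table Subject table.
#' @param covariates Character vector of covariate column names (numeric or
#'   factor), e.g. `c("ttv", "age", "euler")`.
#' @param regions Response columns; default all `vol_` columns.
#' @return Numeric matrix, subjects x regions.
#' @export
residualize <- function(table, covariates, regions = NULL) {
  if (is.null(regions)) regions <- region_columns(table)
  if ("sex" %in% covariates)
    stop("sex must not be residualized out before variance testing",
         call. = FALSE)
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov) > 0)
    stop("missing covariate column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  df <- table[, covariates, drop = FALSE]
  df[] <- lapply(df, function(v) if (is.character(v)) factor(v) else v)
  Y <- as.matrix(table[, regions, drop = FALSE])
  X <- stats::model.matrix(~ ., data = df)
  fit <- stats::lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  colnames(res) <- sub("^vol_", "", regions)
  res
}

#' Levene's test for equality of variances between sexes
#'
#' Classic Levene test: one-way ANOVA on absolute deviations from each
#' group's center (the mean by default; a median center, i.e. the
#' Brown-Forsythe variant, is available via `center`).
#'
#' @param values Numeric vector, typically residualized volumes.
#' @param group Grouping labels (two or more groups, each with >= 2
#'   observations).
#' @param center `"mean"` (classic) or `"median"`.
#' @return A list of class `variance_test`: `F`, `p`, `df`, and
#'   `group_variances`.
#' @export
levene_variance_test <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(table(group) < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  cfun <- if (center == "mean") mean else stats::median
  centers <- tapply(values, group, cfun)
  ad <- abs(values - centers[group])
  ow <- stats::oneway.test(ad ~ group, var.equal = TRUE)
  structure(
    list(F = unname(ow$statistic), p = ow$p.value,
         df = unname(ow$parameter),
         group_variances = tapply(values, group, stats::var),
         center = center),
    class = "variance_test")
}

#' @export
print.variance_test <- function(x, ...) {
  cat(sprintf("Levene's test (center = %s): F(%g, %g) = %.4f, p = %.4g\n",
              x$center, x$df[1], x$df[2], x$F, x$p))
  cat("  group variances:",
      paste(sprintf("%s = %.4g", names(x$group_variances),
                    x$group_variances), collapse = ", "), "\n")
  invisible(x)
}

#' Summary of the direction and size of sex bias
#'
#' Proportions of regions with significant sex differences, the female/male
#' split among them, and the median, SD, and range of the standardized betas
#' by sign (negative = female-biased, positive = male-biased).
#'
#' @param results A `sex_effects` data frame from [fit_sex_effects()].
#' @return A list of class `sex_bias_summary`.
#' @export
summarize_sex_bias <- function(results) {
  if (nrow(results) == 0L) stop("empty results", call. = FALSE)
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    warning("no significant regions; proportions reported as 0")
    pf <- pm <- 0
  } else {
    pf <- 100 * mean(sig$beta_sex < 0)
    pm <- 100 * mean(sig$beta_sex >= 0)
  }
  by_sign <- function(b) {
    if (length(b) == 0L)
      return(c(median = NA_real_, sd = NA_real_, min = NA_real_,
               max = NA_real_))
    c(median = stats::median(b), sd = stats::sd(b), min = min(b),
      max = max(b))
  }
  structure(
    list(pct_significant = 100 * mean(results$significant),
         pct_female_biased_of_sig = pf,
         pct_male_biased_of_sig = pm,
         female_biased = by_sign(results$beta_sex[results$beta_sex < 0]),
         male_biased = by_sign(results$beta_sex[results$beta_sex > 0])),
    class = "sex_bias_summary")
}

#' @export
print.sex_bias_summary <- function(x, ...) {
  cat(sprintf("%.1f%% of regions significant; of these %.1f%% female-biased, %.1f%% male-biased\n",
              x$pct_significant, x$pct_female_biased_of_sig,
              x$pct_male_biased_of_sig))
  cat(sprintf("  female-biased beta: median %.3f (SD %.3f, range %.3f to %.3f)\n",
              x$female_biased["median"], x$female_biased["sd"],
              x$female_biased["min"], x$female_biased["max"]))
  cat(sprintf("  male-biased beta:   median %.3f (SD %.3f, range %.3f to %.3f)\n",
              x$male_biased["median"], x$male_biased["sd"],
              x$male_biased["min"], x$male_biased["max"]))
  invisible(x)
}

#' Keep one subject per family
#'
#' Twin/sibling sensitivity subset: deterministically (seeded) samples one
#' subject from each family so that family structure cannot inflate the
#' effective sample.
#'
#' @param table Subject table with a `family_id` column.
#' @param seed Integer seed; the same seed always selects the same subjects.
#' @param family_col Name of the family column.
#' @return The subsetted table (one row per family).
#' @export
subset_one_per_family <- function(table, seed, family_col = "family_id") {
  if (!family_col %in% names(table))
    stop("missing family column '", family_col, "'", call. = FALSE)
  idx <- with_seed(seed, {
    split_idx <- split(seq_len(nrow(table)), table[[family_col]])
    vapply(split_idx, function(i) if (length(i) == 1L) i else sample(i, 1L),
           integer(1))
  })
  out <- table[sort(unname(idx)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
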