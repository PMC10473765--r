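#' @keywords internal
#' @noRd
new_cor_result <- function(r, t, p, n, method, bend_constant = NA_real_,
                           n_removed = 0L) {
  structure(
    list(r = r, t = t, p = p, n = n, method = method,
         bend_constant = bend_constant, n_removed = n_removed),
    class = "cor_result"
  )
}

#' @export
print.cor_result <- function(x, digits = 4, ...) {
  lab <- switch(x$method,
                percentage_bend = sprintf("Percentage-bend correlation (bend = %g)",
                                          x$bend_constant),
                pearson = "Pearson correlation",
                x$method)
  cat(lab, "\n", sep = "")
  cat(sprintf("  r = %.*f, t = %.*f, p = %.4g, n = %d\n",
              digits, x$r, digits, x$t, x$p, x$n))
  if (x$n_removed > 0)
    cat(sprintf("  (%d incomplete pair(s) removed)\n", x$n_removed))
  invisible(x)
}

# Pairwise deletion of incomplete pairs; errors on degenerate input.
check_pairs <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  n_removed <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  list(x = x, y = y, n = n, n_removed = n_removed)
}

# Robust scale: the m-th order statistic of |x - median(x)|, with
# m = floor((1 - bend) * n + 0.5). Ties are kept as-is (no interpolation).
pb_scale <- function(x, bend_constant) {
  n <- length(x)
  m <- floor((1 - bend_constant) * n + 0.5)
  sort(abs(x - stats::median(x)))[m]
}

# Bend-adjusted location: trims observations whose standardized deviation
# from the median exceeds 1 in absolute value, compensating with the scale.
pb_location <- function(x, bend_constant) {
  omega <- pb_scale(x, bend_constant)
  psi <- (x - stats::median(x)) / omega
  i1 <- sum(psi < -1)
  i2 <- sum(psi > 1)
  sx <- x
  sx[psi < -1 | psi > 1] <- 0
  (sum(sx) + omega * (i2 - i1)) / (length(x) - i1 - i2)
}

#' Percentage-bend correlation
#'
#' Robust correlation that clamps ("bends") standardized deviations beyond a
#' quantile-based robust scale estimate before forming a product-moment
#' statistic, making it far less sensitive to outliers than the Pearson
#' correlation. For each variable the scale is the m-th order statistic of
#' absolute deviations from the median with `m = floor((1 - bend) * n + 0.5)`;
#' deviations are taken about a bend-adjusted location and clamped to
#' \[-1, 1\]. Inference uses `t = r * sqrt((n - 2) / (1 - r^2))` referred to a
#' t distribution on `n - 2` degrees of freedom (two-sided).
#'
#' @param x,y Numeric vectors of equal length. Incomplete pairs are dropped
#'   (pairwise deletion) and the number removed is reported in the result.
#' @param bend_constant Bending proportion in (0, 0.5]; the default 0.2
#'   resists up to 20% contamination in each variable.
#' @return A `cor_result` with elements `r`, `t`, `p`, `n`, `method`,
#'   `bend_constant`, `n_removed`.
#' @examples
#' set.seed(1)
#' x <- rnorm(30); y <- x + rnorm(30)
#' x[1] <- 100  # gross outlier barely moves the estimate
#' percentage_bend_correlation(x, y)
#' @export
percentage_bend_correlation <- function(x, y, bend_constant = 0.2) {
  if (!is.numeric(bend_constant) || length(bend_constant) != 1L ||
      bend_constant <= 0 || bend_constant > 0.5)
    stop("'bend_constant' must be a single number in (0, 0.5]", call. = FALSE)
  pr <- check_pairs(x, y)
  x <- pr$x; y <- pr$y; n <- pr$n
  omx <- pb_scale(x, bend_constant)
  omy <- pb_scale(y, bend_constant)
  if (omx == 0 || omy == 0)
    stop("degenerate input: robust scale estimate is zero", call. = FALSE)
  a <- pmin(pmax((x - pb_location(x, bend_constant)) / omx, -1), 1)
  b <- pmin(pmax((y - pb_location(y, bend_constant)) / omy, -1), 1)
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  new_cor_result(r, tstat, p, n, "percentage_bend", bend_constant,
                 pr$n_removed)
}

#' Pearson correlation with t-based inference
#'
#' Standard product-moment correlation, returned in the same `cor_result`
#' structure as [percentage_bend_correlation()] so the two methods are
#' interchangeable downstream. Incomplete pairs are dropped pairwise.
#'
#' @inheritParams percentage_bend_correlation
#' @return A `cor_result`.
#' @export
pearson_correlation <- function(x, y) {
  pr <- check_pairs(x, y)
  ct <- stats::cor.test(pr$x, pr$y, method = "pearson")
  new_cor_result(unname(ct$estimate), unname(ct$statistic), ct$p.value,
                 pr$n, "pearson", n_removed = pr$n_removed)
}

#' Monte-Carlo permutation p-value
#'
#' Add-one ("+1") permutation p-value estimator:
#' `p = (1 + #(null at least as extreme as observed)) / (n_resamples + 1)`.
#' The +1 convention avoids reporting p = 0 from a finite resample. For
#' `direction = "two_sided"` the smaller of the two tail p-values is doubled
#' and capped at 1.
#'
#' @param observed Observed test statistic (single number).
#' @param null Numeric vector of resampled null statistics.
#' @param direction One of `"two_sided"`, `"greater"`, `"less"`.
#' @return A p-value in (0, 1].
#' @export
permutation_p_value <- function(observed,
                                null,
                                direction = c("two_sided", "greater", "less")) {
  direction <- match.arg(direction)
  if (length(null) == 0L || !is.numeric(null))
    stop("'null' must be a non-empty numeric vector", call. = FALSE)
  if (!is.finite(observed))
    stop("'observed' must be a finite number", call. = FALSE)
  b <- length(null)
  p_ge <- (1 + sum(null >= observed)) / (b + 1)
  p_le <- (1 + sum(null <= observed)) / (b + 1)
  switch(direction,
         greater = p_ge,
         less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

#' Cook's distance for a simple linear regression
#'
#' Per-observation influence for the regression of `y` on `x` with an
#' intercept: `d_i = (e_i^2 / (k * s^2)) * (h_ii / (1 - h_ii)^2)` with k = 2
#' estimated coefficients, residuals `e`, leverages `h`, and residual mean
#' square `s^2`. Used to flag regions that single-handedly drive a
#' cross-region correlation.
#'
#' @param x Predictor values (non-constant, length >= 4).
#' @param y Response values, same length as `x`.
#' @return Numeric vector of Cook's distances (all >= 0), named after `x`
#'   if it has names.
#' @export
cooks_distance_simple <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  n <- length(x)
  if (n < 4L)
    stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate design: 'x' is constant", call. = FALSE)
  k <- 2L
  xc <- x - mean(x)
  h <- 1 / n + xc^2 / sum(xc^2)
  beta1 <- sum(xc * y) / sum(xc^2)
  e <- y - (mean(y) + beta1 * xc)
  s2 <- sum(e^2) / (n - k)
  d <- (e^2 / (k * s2)) * (h / (1 - h)^2)
  names(d) <- names(x)
  d
}
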