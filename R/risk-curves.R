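#' Winsorize a numeric vector at percentile limits
#'
#' Values below the `lower_pct` percentile are raised to it and values above
#' the `upper_pct` percentile lowered to it (default 1st/99th), limiting the
#' influence of long uninformative tails. Percentiles use the linear
#' interpolation convention ([stats::quantile()] `type = 7`).
#'
#' Because the percentiles are interpolated between order statistics,
#' re-estimating them on already-clipped data can move the limits inward by
#' up to one order-statistic gap; pass `limits` (e.g. the `limits` attribute
#' of a previous call) to re-apply exactly the same clipping, which is
#' strictly idempotent.
#'
#' @param values Numeric vector (>= 2 values).
#' @param lower_pct,upper_pct Percentile limits in \[0, 100\],
#'   `lower_pct < upper_pct`.
#' @param limits Optional fixed `c(low, high)` clipping limits overriding the
#'   percentile estimation.
#' @return Clipped vector, same length/order (`NA`s passed through), with the
#'   applied limits in attribute `limits`.
#' @export
#' @examples
#' range(winsorize(1:100))
winsorize <- function(values, lower_pct = 1, upper_pct = 99, limits = NULL) {
  if (lower_pct < 0 || upper_pct > 100 || lower_pct >= upper_pct) {
    abort_cfg("winsorization percentiles must satisfy 0 <= lower_pct < upper_pct <= 100")
  }
  if (sum(is.finite(values)) < 2) {
    abort_cfg("winsorize needs at least 2 finite values")
  }
  if (is.null(limits)) {
    limits <- quantile(values, c(lower_pct, upper_pct) / 100, na.rm = TRUE,
                       type = 7, names = FALSE)
  } else if (length(limits) != 2 || limits[1] > limits[2]) {
    abort_cfg("limits must be an increasing c(low, high) pair")
  }
  out <- pmin(pmax(values, limits[1]), limits[2])
  attr(out, "limits") <- unname(limits)
  out
}

#' Loess risk curve for a binary outcome
#'
#' Locally weighted regression (degree 2, tricube weights) of the 0/1 outcome
#' on a (winsorized) predictor, evaluated on an evenly spaced grid across the
#' predictor range, with a pointwise normal-approximation 95% confidence
#' band. This is the smoothed-risk analysis surface: the fitted value at x
#' estimates the event probability at that predictor level.
#'
#' @param x Numeric predictor (winsorize first; see [risk_curve()] for the
#'   data-frame interface that does both).
#' @param y Binary outcome, 0/1 or logical.
#' @param span Loess span (fraction of points in each local window), default
#'   0.75.
#' @param degree Local polynomial degree, default 2.
#' @param grid_n Number of grid points, default 100.
#' @param predictor_name Label carried into the result.
#' @return A `risk_curve` tibble: `x`, `fitted`, `band_low`, `band_high`;
#'   attributes `predictor`, `span`, `n`.
#' @export
fit_risk_curve <- function(x, y, span = 0.75, degree = 2, grid_n = 100,
                           predictor_name = "predictor") {
  if (length(x) != length(y)) abort_cfg("x and y must have the same length")
  y <- as.numeric(y)
  if (!all(y[is.finite(y)] %in% c(0, 1))) {
    abort_cfg("y must be binary (0/1 or logical)")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  min_n <- max(10, ceiling(degree + 2) / span)
  if (length(x) < min_n) {
    stop(sprintf("too few observations (%d) for a loess window with span %.2f",
                 length(x), span), call. = FALSE)
  }
  fit <- loess(y ~ x, span = span, degree = degree,
               family = "gaussian", surface = "direct")
  grid <- seq(min(x), max(x), length.out = grid_n)
  pred <- predict(fit, newdata = data.frame(x = grid), se = TRUE)
  zcrit <- qnorm(0.975)
  se <- ifelse(is.finite(pred$se.fit), pred$se.fit, 0)
  out <- tibble::tibble(
    x = grid,
    fitted = as.numeric(pred$fit),
    band_low = as.numeric(pred$fit) - zcrit * se,
    band_high = as.numeric(pred$fit) + zcrit * se
  )
  if (any(!is.finite(out$fitted))) {
    stop("loess produced non-finite fitted values", call. = FALSE)
  }
  attr(out, "predictor") <- predictor_name
  attr(out, "span") <- span
  attr(out, "n") <- length(x)
  class(out) <- c("risk_curve", class(out))
  out
}

#' Winsorized loess risk curve from a cohort
#'
#' Data-frame-first wrapper: extracts the predictor (a lipid species/ratio
#' via [lipid_predictors()] naming, a CERT score, or a numeric column),
#' winsorizes it at the 1st/99th percentiles, derives the outcome indicator
#' (prevalent via [classify_prevalent()], or new-onset among the
#' hypertension-free), and fits [fit_risk_curve()].
#'
#' @param cohort Cohort tibble.
#' @param predictor Predictor name.
#' @param outcome `"prevalent"` or `"new_onset"`.
#' @param lower_pct,upper_pct Winsorization percentiles.
#' @inheritParams fit_risk_curve
#' @return A `risk_curve`.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_finrisk_config(n_subjects = 600, seed = 3))
#' rc <- risk_curve(cohort, "cer_18_0", "prevalent")
#' head(as.data.frame(rc))
risk_curve <- function(cohort, predictor, outcome = c("prevalent", "new_onset"),
                       lower_pct = 1, upper_pct = 99, span = 0.75,
                       degree = 2, grid_n = 100) {
  outcome <- match.arg(outcome)
  x <- predictor_column(cohort, predictor, standardize = FALSE)
  prevalent <- classify_prevalent(cohort$sbp, cohort$dbp, cohort$bp_lowering_tx)
  if (outcome == "prevalent") {
    y <- as.numeric(prevalent)
  } else {
    x <- x[!prevalent]
    y <- as.numeric(cohort$event_new_onset[!prevalent])
  }
  x <- winsorize(x, lower_pct, upper_pct)
  fit_risk_curve(x, y, span = span, degree = degree, grid_n = grid_n,
                 predictor_name = predictor)
}
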