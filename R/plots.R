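# ggplot2 presentation layer; no tested analysis logic lives here.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a loess risk curve with its confidence band
#'
#' @param object A `risk_curve` from [risk_curve()] or [fit_risk_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot risk_curve
#' @export
autoplot.risk_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$fitted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_low,
                                      ymax = .data$band_high),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = lipid_label_safe(attr(object, "predictor")),
                  y = "Estimated hypertension risk",
                  title = sprintf("Loess risk curve (span %.2f, n = %d)",
                                  attr(object, "span"), attr(object, "n"))) +
    ggplot2::theme_minimal()
}

lipid_label_safe <- function(x) {
  out <- tryCatch(lipid_label(x), error = function(e) x)
  ifelse(is.na(out) | out == "NA", x, out)
}

#' Distribution of score totals by risk category
#'
#' @param object Output of [score_cohort()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cert_scores
#' @export
autoplot.cert_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$total, fill = .data$category)) +
    ggplot2::geom_bar() +
    ggplot2::scale_x_continuous(breaks = 0:12, limits = c(-0.5, 12.5)) +
    ggplot2::labs(x = paste(object$score[1], "total (points)"), y = "Subjects",
                  fill = "CVD risk") +
    ggplot2::theme_minimal()
}

#' Forest plot of association-suite results
#'
#' @param results Output of [run_association_suite()].
#' @param outcome Which outcome to display.
#' @return A ggplot with point estimates and 95% CIs on a log scale.
#' @export
plot_association_forest <- function(results, outcome = "prevalent") {
  dat <- results[results$outcome == outcome, ]
  if ("analysis" %in% names(dat)) dat <- dat[dat$analysis == "main", ]
  dat$label <- vapply(dat$predictor, lipid_label_safe, character(1))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$label,
                                    colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = if (outcome == "prevalent") "Odds ratio (95% CI)"
                  else "Hazard ratio (95% CI)",
                  y = NULL, colour = "Adjustment") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
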