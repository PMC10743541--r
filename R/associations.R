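#' Classify prevalent hypertension at baseline
#'
#' A subject is prevalent-hypertensive when currently on blood-pressure
#' lowering treatment, or SBP >= 140 mmHg, or DBP >= 90 mmHg.
#'
#' @param sbp,dbp Systolic/diastolic blood pressure, mmHg (means of three
#'   readings).
#' @param bp_tx Logical, current BP-lowering drug treatment.
#' @return Logical vector.
#' @export
#' @examples
#' classify_prevalent(c(150, 120, 139), c(85, 70, 89), c(FALSE, TRUE, FALSE))
classify_prevalent <- function(sbp, dbp, bp_tx) {
  if (any(sbp <= 0 | dbp <= 0, na.rm = TRUE)) {
    abort_cfg("blood pressures must be positive")
  }
  bp_tx | sbp >= 140 | dbp >= 90
}

#' Standardize a predictor to mean 0, SD 1
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Standardized vector (order preserved; `NA`s passed through).
#' @export
standardize_predictor <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2) {
    abort_cfg("cannot standardize a constant (or near-empty) predictor")
  }
  (values - mean(v)) / sd(v)
}

adjustment_models <- function() c("unadjusted", "M1", "M2", "M3")

# Covariate list per adjustment model and outcome. In the Cox setting age is
# the timescale and sex a stratum, so M1 has no meaning and M2/M3 drop
# age/sex from the covariate list.
adjustment_covariates <- function(model, outcome) {
  model <- match.arg(model, adjustment_models())
  outcome <- match.arg(outcome, c("prevalent", "new_onset"))
  lipids_cov <- c("tc", "hdl", "ldl")
  extra <- c("bmi", "smoking", "diabetes", "lipid_lowering_tx")
  if (outcome == "prevalent") {
    switch(model,
           unadjusted = character(0),
           M1 = c("age_baseline", "sex"),
           M2 = c("age_baseline", "sex", lipids_cov),
           M3 = c("age_baseline", "sex", lipids_cov, extra))
  } else {
    if (model == "M1") {
      abort_cfg("M1 is not defined for the new-onset analysis: age is the timescale and sex enters as a stratum")
    }
    switch(model,
           unadjusted = character(0),
           M2 = lipids_cov,
           M3 = c(lipids_cov, extra))
  }
}

# Add the predictor column named `predictor` to the cohort: CERT totals as
# raw points (quartiles fitted once on the whole input cohort), lipid
# species/ratios standardized per SD by default.
predictor_column <- function(cohort, predictor, standardize = NULL) {
  if (predictor %in% c("CERT1", "CERT2")) {
    scores <- suppressWarnings(score_cohort(cohort, predictor))
    out <- rep(NA_real_, nrow(cohort))
    out[match(scores$subject_id, cohort$subject_id)] <- scores$total
    if (isTRUE(standardize)) out <- standardize_predictor(out)
    return(out)
  }
  if (predictor %in% lipid_predictors()) {
    parts <- parse_lipid_predictor(predictor)
    spec <- tibble::tibble(component = predictor, numerator = parts$numerator,
                           denominator = parts$denominator)
    out <- component_value(cohort, spec)
    if (is.null(standardize) || isTRUE(standardize)) {
      out <- standardize_predictor(out)
    }
    return(out)
  }
  if (predictor %in% names(cohort)) {
    out <- as.numeric(cohort[[predictor]])
    if (isTRUE(standardize)) out <- standardize_predictor(out)
    return(out)
  }
  abort_cfg(paste0(
    "unknown predictor '", predictor, "'; valid names are CERT1, CERT2, ",
    paste(lipid_predictors(), collapse = ", "), ", or a cohort column"))
}

new_cert_fit <- function(fit, predictor, outcome, model_label, effect_type,
                         n_used, n_excluded, n_events = NA_integer_,
                         term = ".predictor") {
  est <- coef(fit)[term]
  se <- sqrt(diag(vcov(fit))[term])
  if (!is.finite(est) || !is.finite(se) || abs(est) > 15) {
    stop(sprintf("model for '%s' (%s, %s) did not converge to a usable estimate (possible complete separation); |log-effect| = %.2f",
                 predictor, outcome, model_label, abs(est)), call. = FALSE)
  }
  z <- est / se
  result <- tibble::tibble(
    predictor = predictor,
    outcome = outcome,
    model = model_label,
    effect_type = effect_type,
    estimate = exp(unname(est)),
    ci_low = exp(unname(est - qnorm(0.975) * se)),
    ci_high = exp(unname(est + qnorm(0.975) * se)),
    p_value = unname(2 * pnorm(-abs(z))),
    n_used = n_used,
    significant = unname(2 * pnorm(-abs(z)) < 0.05)
  )
  structure(list(result = result, fit = fit, predictor = predictor,
                 outcome = outcome, model = model_label,
                 n_used = n_used, n_excluded = n_excluded,
                 n_events = n_events),
            class = "cert_fit")
}

#' @export
print.cert_fit <- function(x, ...) {
  cat(sprintf("<cert_fit> %s ~ %s (%s), n = %d\n",
              x$outcome, x$predictor, x$model, x$n_used))
  print(x$result)
  invisible(x)
}

#' Tidy an association fit
#'
#' One row in the association-result schema: predictor, outcome, model,
#' effect type (OR/HR), point estimate, Wald 95% CI, p-value, n used and the
#' p < 0.05 significance flag.
#'
#' @param x A `cert_fit` from [fit_prevalent()] or [fit_new_onset()].
#' @param ... Unused.
#' @return One-row tibble.
#' @method tidy cert_fit
#' @export
tidy.cert_fit <- function(x, ...) x$result

#' Model-level summary of an association fit
#'
#' @param x A `cert_fit`.
#' @param ... Unused.
#' @return One-row tibble with subject accounting and likelihood summaries.
#' @method glance cert_fit
#' @export
glance.cert_fit <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, n_excluded = x$n_excluded,
                 n_events = x$n_events,
                 loglik = as.numeric(stats::logLik(x$fit)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Logistic model for prevalent hypertension
#'
#' Fits maximum-likelihood logistic regression of the prevalent-hypertension
#' indicator (derived via [classify_prevalent()]) on one predictor plus the
#' adjustment covariates: unadjusted, M1 (age + sex), M2 (M1 + TC + HDL +
#' LDL) or M3 (M2 + BMI + smoking + diabetes + lipid-lowering treatment).
#' CERT totals enter as raw points; lipid species/ratios are standardized
#' per SD. The odds ratio is per unit of the predictor with a Wald 95% CI.
#'
#' @param cohort Cohort tibble.
#' @param predictor `"CERT1"`, `"CERT2"`, one of [lipid_predictors()], or a
#'   numeric cohort column name.
#' @param model Adjustment label, one of `"unadjusted"`, `"M1"`, `"M2"`,
#'   `"M3"`.
#' @param standardize Override the default predictor scaling (`TRUE`/`FALSE`).
#' @param subset_sex Optional `"male"`/`"female"` to fit within one sex (sex
#'   is then dropped from the covariates).
#' @return A `cert_fit`; see [tidy.cert_fit()].
#' @export
fit_prevalent <- function(cohort, predictor, model = "unadjusted",
                          standardize = NULL, subset_sex = NULL) {
  model <- match.arg(model, adjustment_models())
  covars <- adjustment_covariates(model, "prevalent")
  dat <- dplyr::mutate(cohort,
                       .outcome = classify_prevalent(sbp, dbp, bp_lowering_tx),
                       .predictor = predictor_column(cohort, predictor, standardize))
  if (!is.null(subset_sex)) {
    dat <- dat[dat$sex == subset_sex, , drop = FALSE]
    covars <- setdiff(covars, "sex")
  }
  keep <- complete.cases(dat[, c(".outcome", ".predictor", covars)])
  used <- dat[keep, , drop = FALSE]
  fml <- stats::reformulate(c(".predictor", covars), response = ".outcome")
  fit <- glm(fml, family = binomial(), data = used)
  if (!fit$converged) {
    stop(sprintf("logistic model for '%s' (%s) failed to converge (possible complete separation)",
                 predictor, model), call. = FALSE)
  }
  new_cert_fit(fit, predictor, "prevalent", model, "OR",
               n_used = nrow(used), n_excluded = nrow(dat) - nrow(used),
               n_events = sum(used$.outcome))
}

#' Cox model for new-onset hypertension with age as the timescale
#'
#' Excludes prevalent subjects, then fits a proportional-hazards model with
#' attained age as the time axis: entry at baseline age (left truncation),
#' exit at onset or censoring age, Efron tie handling, sex as a stratum.
#' Adjustment models: unadjusted, M2 (TC + HDL + LDL) and M3 (M2 + BMI +
#' smoking + diabetes + lipid-lowering treatment); M1 is not fitted because
#' age is the timescale and sex is a stratum.
#'
#' @inheritParams fit_prevalent
#' @return A `cert_fit` with hazard ratios; see [tidy.cert_fit()].
#' @export
fit_new_onset <- function(cohort, predictor, model = "unadjusted",
                          standardize = NULL, subset_sex = NULL) {
  model <- match.arg(model, adjustment_models())
  covars <- adjustment_covariates(model, "new_onset")
  dat <- dplyr::mutate(cohort,
                       .prevalent = classify_prevalent(sbp, dbp, bp_lowering_tx),
                       .predictor = predictor_column(cohort, predictor, standardize))
  dat <- dat[!dat$.prevalent, , drop = FALSE]
  if (!is.null(subset_sex)) dat <- dat[dat$sex == subset_sex, , drop = FALSE]
  bad <- which(dat$age_at_event_or_censor <= dat$age_baseline)
  if (length(bad) > 0) {
    stop(sprintf("exit age <= entry age for subject %s", dat$subject_id[bad[1]]),
         call. = FALSE)
  }
  keep <- complete.cases(dat[, c(".predictor", "age_baseline",
                                 "age_at_event_or_censor", "event_new_onset",
                                 covars)])
  used <- dat[keep, , drop = FALSE]
  if (sum(used$event_new_onset) == 0) {
    stop("no new-onset events in the analysis set", call. = FALSE)
  }
  rhs <- c(".predictor", covars,
           if (is.null(subset_sex)) "survival::strata(sex)")
  fml <- stats::as.formula(paste(
    "survival::Surv(age_baseline, age_at_event_or_censor, event_new_onset) ~",
    paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = used, ties = "efron")
  new_cert_fit(fit, predictor, "new_onset", model, "HR",
               n_used = nrow(used), n_excluded = nrow(dat) - nrow(used),
               n_events = sum(used$event_new_onset))
}

#' Run the full association suite
#'
#' Fits every predictor x outcome x adjustment-model combination of the
#' published analysis layout: CERT1/CERT2 and the 13 lipid species/ratios,
#' prevalent (logistic, unadjusted/M1/M2/M3) and new-onset (Cox,
#' unadjusted/M2/M3 -- M1 is skipped because age is the timescale). Results
#' come back in a stable order with a significance flag at p < 0.05.
#'
#' @param cohort Cohort tibble.
#' @param predictors Character vector; default CERT1, CERT2 and
#'   [lipid_predictors()].
#' @param outcomes Subset of `c("prevalent", "new_onset")`.
#' @param models Subset of the adjustment labels.
#' @param sex_analyses When `TRUE`, additionally fits male-only and
#'   female-only models and a sex x predictor interaction (Wald p) for each
#'   combination.
#' @return Tibble: predictor, outcome, model, analysis (`"main"`, `"male"`,
#'   `"female"`, `"sex_interaction"`), effect_type, estimate, ci_low,
#'   ci_high, p_value, n_used, significant.
#' @export
run_association_suite <- function(cohort,
                                  predictors = c("CERT1", "CERT2", lipid_predictors()),
                                  outcomes = c("prevalent", "new_onset"),
                                  models = adjustment_models(),
                                  sex_analyses = FALSE) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  models <- match.arg(models, adjustment_models(), several.ok = TRUE)
  valid <- c("CERT1", "CERT2", lipid_predictors())
  bad <- setdiff(predictors, valid)
  if (length(bad) > 0) {
    abort_cfg(paste0("unknown predictor(s): ", paste(bad, collapse = ", "),
                     "; valid names: ", paste(valid, collapse = ", ")))
  }
  if (length(predictors) == 0) {
    return(tibble::tibble(predictor = character(), outcome = character(),
                          model = character(), analysis = character(),
                          effect_type = character(), estimate = double(),
                          ci_low = double(), ci_high = double(),
                          p_value = double(), n_used = integer(),
                          significant = logical()))
  }
  grid <- tidyr::expand_grid(predictor = predictors, outcome = outcomes,
                             model = models)
  grid <- grid[!(grid$outcome == "new_onset" & grid$model == "M1"), ]

  one <- function(predictor, outcome, model) {
    fitter <- if (outcome == "prevalent") fit_prevalent else fit_new_onset
    main <- tidy(fitter(cohort, predictor, model))
    main$analysis <- "main"
    rows <- list(main)
    if (sex_analyses) {
      for (s in c("male", "female")) {
        r <- tidy(fitter(cohort, predictor, model, subset_sex = s))
        r$analysis <- s
        rows <- c(rows, list(r))
      }
      rows <- c(rows, list(sex_interaction_row(cohort, predictor, outcome, model)))
    }
    dplyr::bind_rows(rows)
  }
  out <- purrr::pmap_dfr(grid, one)
  dplyr::relocate(out, "analysis", .after = "model")
}

# Wald test of the sex x predictor interaction, keeping the main-effects
# structure of the corresponding adjustment model.
sex_interaction_row <- function(cohort, predictor, outcome, model) {
  if (outcome == "prevalent") {
    covars <- adjustment_covariates(model, "prevalent")
    dat <- dplyr::mutate(cohort,
                         .outcome = classify_prevalent(sbp, dbp, bp_lowering_tx),
                         .predictor = predictor_column(cohort, predictor, NULL))
    keep <- complete.cases(dat[, c(".outcome", ".predictor", "sex", covars)])
    used <- dat[keep, , drop = FALSE]
    fml <- stats::reformulate(c(".predictor * sex", setdiff(covars, "sex")),
                              response = ".outcome")
    fit <- glm(fml, family = binomial(), data = used)
    effect_type <- "OR"
    n_events <- sum(used$.outcome)
  } else {
    covars <- adjustment_covariates(model, "new_onset")
    dat <- dplyr::mutate(cohort,
                         .prevalent = classify_prevalent(sbp, dbp, bp_lowering_tx),
                         .predictor = predictor_column(cohort, predictor, NULL))
    dat <- dat[!dat$.prevalent, , drop = FALSE]
    keep <- complete.cases(dat[, c(".predictor", "age_baseline",
                                   "age_at_event_or_censor",
                                   "event_new_onset", "sex", covars)])
    used <- dat[keep, , drop = FALSE]
    fml <- stats::as.formula(paste(
      "survival::Surv(age_baseline, age_at_event_or_censor, event_new_onset) ~",
      paste(c(".predictor * sex", covars, "survival::strata(sex)"),
            collapse = " + ")))
    fit <- survival::coxph(fml, data = used, ties = "efron")
    effect_type <- "HR"
    n_events <- sum(used$event_new_onset)
  }
  term <- grep("^\\.predictor:sex", names(coef(fit)), value = TRUE)[1]
  est <- coef(fit)[term]
  se <- sqrt(diag(vcov(fit))[term])
  z <- est / se
  p <- unname(2 * pnorm(-abs(z)))
  tibble::tibble(predictor = predictor, outcome = outcome, model = model,
                 analysis = "sex_interaction",
                 effect_type = paste0(effect_type, "_interaction"),
                 estimate = exp(unname(est)),
                 ci_low = exp(unname(est - qnorm(0.975) * se)),
                 ci_high = exp(unname(est + qnorm(0.975) * se)),
                 p_value = p, n_used = nrow(used),
                 significant = p < 0.05)
}

#' Widen suite results into the published two-outcome layout
#'
#' One row per predictor x model, with OR (95% CI)/p for the prevalent study
#' and HR (95% CI)/p for the new-onset study side by side (the new-onset M1
#' cells stay empty).
#'
#' @param results Output of [run_association_suite()].
#' @return Wide tibble.
#' @export
format_association_table <- function(results) {
  main <- results[!("analysis" %in% names(results)) | results$analysis == "main", ]
  fmt <- function(est, lo, hi) sprintf("%.2f (%.2f-%.2f)", est, lo, hi)
  main <- dplyr::mutate(main,
                        cell = fmt(estimate, ci_low, ci_high),
                        p = signif(p_value, 2))
  wide <- tidyr::pivot_wider(
    dplyr::select(main, dplyr::all_of(c("predictor", "model", "outcome", "cell", "p"))),
    names_from = "outcome", values_from = c("cell", "p"))
  names(wide) <- sub("^cell_prevalent$", "or_95ci", names(wide))
  names(wide) <- sub("^cell_new_onset$", "hr_95ci", names(wide))
  wide
}
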