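#' Simulate a synthetic survey cohort
#'
#' Draws `n_subjects` records with the statistical structure the downstream
#' analyses assume: truncated-normal age (moment-matched so the configured
#' mean/SD hold after restriction to the age range), Bernoulli sex,
#' multivariate log-normal lipids with the configured correlation,
#' truncated-normal / log-normal clinical covariates, prevalent hypertension
#' from the configured logistic model, blood pressure and treatment drawn
#' jointly with prevalent status so the threshold rule (treatment or SBP >=
#' 140 or DBP >= 90) agrees with the simulated indicator by construction, and
#' new-onset hypertension from a Weibull proportional-hazards model on the
#' attained-age timescale with independent exponential death censoring and
#' administrative censoring at `followup_years`.
#'
#' Output is byte-identical for identical configurations: one master seed,
#' with deterministic sub-streams per variable block.
#'
#' @param config A `cert_sim_config`, see [default_finrisk_config()].
#' @return Tibble of cohort records in the documented column order (see
#'   [cohort_columns()]).
#' @export
#' @examples
#' cohort <- simulate_cohort(default_finrisk_config(n_subjects = 300, seed = 7))
#' mean(classify_prevalent(cohort$sbp, cohort$dbp, cohort$bp_lowering_tx))
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- as.integer(config$n_subjects)
  sub <- function(block) set.seed(derive_seed(config$seed, block))

  # -- demographics -----------------------------------------------------
  sub(1)
  ap <- tnorm_params(config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  age <- rtnorm(n, ap["mean"], ap["sd"], config$age_range[1], config$age_range[2])
  sex <- ifelse(runif(n) < config$male_fraction, "male", "female")

  # -- lipids -----------------------------------------------------------
  sub(2)
  z <- MASS::mvrnorm(n, mu = rep(0, 7), Sigma = config$lipid_correlation)
  z <- matrix(z, nrow = n)
  lip <- exp(sweep(sweep(z, 2, config$lipid_log_sds, `*`), 2,
                   config$lipid_log_means, `+`))
  colnames(lip) <- lipid_species()

  # -- clinical covariates ---------------------------------------------
  sub(3)
  cp <- config$covariate_params
  draw_cont <- function(p) {
    if (identical(p$dist, "lognormal")) {
      lp <- lnorm_params(p$mean, p$sd)
      exp(rnorm(n, lp["meanlog"], lp["sdlog"]))
    } else {
      tp <- tnorm_params(p$mean, p$sd, p$min %||% -Inf, Inf)
      rtnorm(n, tp["mean"], tp["sd"], p$min %||% -Inf, Inf)
    }
  }
  bmi <- draw_cont(cp$bmi); waist <- draw_cont(cp$waist)
  tg <- draw_cont(cp$tg); tc <- draw_cont(cp$tc)
  hdl <- draw_cont(cp$hdl); ldl <- draw_cont(cp$ldl)
  crp <- draw_cont(cp$crp)
  smoking <- runif(n) < cp$smoking$prevalence
  diabetes <- runif(n) < cp$diabetes$prevalence
  lipid_lowering_tx <- runif(n) < cp$lipid_lowering_tx$prevalence

  cohort <- tibble::tibble(
    subject_id = sprintf("S%06d", seq_len(n)),
    age_baseline = age, sex = sex
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(lip))
  cohort$bmi <- bmi; cohort$waist <- waist; cohort$tg <- tg
  cohort$tc <- tc; cohort$hdl <- hdl; cohort$ldl <- ldl; cohort$crp <- crp
  cohort$smoking <- smoking; cohort$diabetes <- diabetes
  cohort$lipid_lowering_tx <- lipid_lowering_tx

  # -- CERT scores driving the outcome models ---------------------------
  # Quartiles need >= 4 subjects; below that the score contribution is zero.
  if (n >= 4) {
    cert1 <- suppressWarnings(score_cohort(cohort, "CERT1"))$total
    cert2 <- suppressWarnings(score_cohort(cohort, "CERT2"))$total
  } else {
    cert1 <- cert2 <- rep(0L, n)
  }

  covs <- list(age = age, male = as.numeric(sex == "male"), bmi = bmi,
               waist = waist, tg = tg, tc = tc, hdl = hdl, ldl = ldl,
               crp = crp, smoking = as.numeric(smoking),
               diabetes = as.numeric(diabetes),
               lipid_lowering_tx = as.numeric(lipid_lowering_tx),
               cert1 = cert1, cert2 = cert2)
  lin_pred <- function(coefs) {
    terms <- setdiff(names(coefs), "intercept")
    bad <- setdiff(terms, names(covs))
    if (length(bad) > 0) {
      abort_cfg(paste0("unknown coefficient name(s): ",
                       paste(bad, collapse = ", ")))
    }
    lp <- rep(unname(coefs["intercept"] %||% 0), n)
    if (is.na(lp[1])) lp <- rep(0, n)
    for (t in terms) lp <- lp + coefs[[t]] * covs[[t]]
    lp
  }

  # -- prevalent hypertension -------------------------------------------
  sub(4)
  lp_prev <- lin_pred(config$prevalent_logit_coefs)
  prevalent <- runif(n) < plogis(lp_prev)

  # -- blood pressure, consistent with prevalent status -----------------
  sub(5)
  bp <- config$bp_params
  sbp <- dbp <- numeric(n)
  bp_tx <- logical(n)
  i0 <- which(!prevalent)
  if (length(i0) > 0) {
    sbp[i0] <- rtnorm(length(i0), bp$normo["sbp_mean"], bp$normo["sbp_sd"],
                      85, 140 - 1e-6)
    dbp[i0] <- rtnorm(length(i0), bp$normo["dbp_mean"], bp$normo["dbp_sd"],
                      45, pmin(90 - 1e-6, sbp[i0] - 5))
  }
  i1 <- which(prevalent)
  if (length(i1) > 0) {
    treated <- runif(length(i1)) < bp$treated_fraction
    bp_tx[i1] <- treated
    it <- i1[treated]; iu <- i1[!treated]
    if (length(it) > 0) {
      sbp[it] <- rtnorm(length(it), bp$hyper["sbp_mean"], bp$hyper["sbp_sd"],
                        95, 250)
      dbp[it] <- rtnorm(length(it), bp$hyper["dbp_mean"], bp$hyper["dbp_sd"],
                        45, sbp[it] - 5)
    }
    if (length(iu) > 0) {
      # untreated prevalent cases must satisfy the BP threshold rule
      sbp[iu] <- rtnorm(length(iu), bp$hyper["sbp_mean"], bp$hyper["sbp_sd"],
                        140, 250)
      dbp[iu] <- rtnorm(length(iu), bp$hyper["dbp_mean"], bp$hyper["dbp_sd"],
                        45, sbp[iu] - 5)
    }
  }
  cohort$bp_lowering_tx <- bp_tx
  cohort$sbp <- sbp
  cohort$dbp <- dbp

  # -- new-onset hypertension on the age timescale ----------------------
  sub(6)
  hz <- config$baseline_hazard_params
  k <- unname(hz["shape"]); lam <- unname(hz["scale"])
  lp_inc <- lin_pred(config$incident_log_hr_coefs)
  # Conditional Weibull onset age given event-free at baseline age.
  u <- rexp(n)
  onset_age <- lam * ((age / lam)^k + u / exp(lp_inc))^(1 / k)
  death_t <- if (config$death_rate > 0) rexp(n, config$death_rate) else rep(Inf, n)
  fu <- config$followup_years
  censor_age <- pmin(age + death_t, age + fu)
  event <- !prevalent & onset_age <= censor_age
  exit_age <- ifelse(event, onset_age, pmin(censor_age, age + fu))
  cohort$event_new_onset <- event
  cohort$age_at_event_or_censor <- exit_age
  cohort$died <- death_t <= fu

  cohort[, names(cohort_columns())]
}
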