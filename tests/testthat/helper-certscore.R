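# Shared fixtures and independent oracles, all built in code.

quick_cohort <- function(n = 400, seed = 1, ...) {
  simulate_cohort(default_finrisk_config(n_subjects = n, seed = seed, ...))
}

# Brute-force linear-interpolation quantile on the sorted list: position
# h = (n-1)p + 1 between order statistics. Independent of stats::quantile.
quantile_oracle <- function(x, p) {
  sx <- sort(x)
  vapply(p, function(pp) {
    h <- (length(sx) - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    sx[lo] + (h - lo) * (sx[hi] - sx[lo])
  }, numeric(1))
}

# Cox partial log-likelihood with left truncation, no ties.
cox_partial_loglik <- function(beta, entry, exit, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- entry < exit[i] & exit >= exit[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Hand-built cohort rows with valid defaults; every argument recycles to n.
make_cohort <- function(n, sbp = 120, dbp = 70, bp_tx = FALSE,
                        event = FALSE, age = 50, exit_age = NULL,
                        sex = "female", died = FALSE) {
  exit_age <- exit_age %||% (rep(age, length.out = n) + 5)
  lip <- stats::setNames(
    as.data.frame(lapply(seq_along(lipid_species()), function(j) {
      0.5 + 0.13 * j + 0.01 * seq_len(n)
    })), lipid_species())
  out <- tibble::tibble(
    subject_id = sprintf("H%04d", seq_len(n)),
    age_baseline = rep(age, length.out = n),
    sex = rep(sex, length.out = n)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(lip))
  out$bmi <- 26; out$waist <- 88; out$tg <- 1.4; out$tc <- 5.6
  out$hdl <- 1.5; out$ldl <- 3.5; out$crp <- 2
  out$smoking <- FALSE; out$diabetes <- FALSE
  out$lipid_lowering_tx <- FALSE
  out$bp_lowering_tx <- rep(bp_tx, length.out = n)
  out$sbp <- rep(sbp, length.out = n)
  out$dbp <- rep(dbp, length.out = n)
  out$event_new_onset <- rep(event, length.out = n)
  out$age_at_event_or_censor <- rep(exit_age, length.out = n)
  out$died <- rep(died, length.out = n)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
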