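test_that("prevalent classification follows the threshold-or-treatment rule", {
  expect_true(classify_prevalent(150, 85, FALSE))
  expect_true(classify_prevalent(120, 70, TRUE))
  expect_false(classify_prevalent(139, 89, FALSE))
  expect_true(classify_prevalent(140, 70, FALSE))
  expect_true(classify_prevalent(120, 90, FALSE))
  expect_error(classify_prevalent(-1, 70, FALSE), "positive")
})

test_that("standardization gives mean 0 / SD 1 and is affine invariant", {
  z <- standardize_predictor(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize_predictor(z), z)
  x <- rnorm(50)
  expect_equal(standardize_predictor(3.7 * x - 11),
               standardize_predictor(x))
  expect_error(standardize_predictor(rep(2, 10)), "constant")
})

test_that("one-binary-predictor logistic OR equals the 2x2 cross-product ratio", {
  # exposed: 20 events / 100; unexposed: 10 events / 100
  ch <- make_cohort(200,
                    sbp = c(rep(150, 20), rep(120, 80),
                            rep(150, 10), rep(120, 90)))
  ch$expo <- rep(c(1, 0), each = 100)
  fit <- fit_prevalent(ch, "expo", "unadjusted")
  res <- tidy(fit)
  expect_equal(res$estimate, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_equal(res$estimate, 2.25, tolerance = 1e-6)
  expect_equal(res$effect_type, "OR")
  expect_equal(res$n_used, 200)
})

test_that("tiny-cohort Cox log-HR matches grid-search partial likelihood", {
  ch <- make_cohort(5, age = c(40, 42, 45, 48, 50),
                    exit_age = c(44, 49, 50.5, 52, 58),
                    event = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  ch$biom <- c(0.4, 1.2, 1.3, 0.9, 1.5)
  fit <- fit_new_onset(ch, "biom", "unadjusted", standardize = FALSE)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, cox_partial_loglik, numeric(1),
               entry = ch$age_baseline, exit = ch$age_at_event_or_censor,
               event = ch$event_new_onset, x = ch$biom)
  beta_grid <- grid[which.max(ll)]
  expect_equal(log(tidy(fit)$estimate), beta_grid, tolerance = 1e-3)

  # three subjects, one event
  ch3 <- make_cohort(3, age = c(40, 41, 42), exit_age = c(44, 46, 47),
                     event = c(TRUE, FALSE, FALSE))
  ch3$biom <- c(1.2, 0.5, 1.5)
  f3 <- fit_new_onset(ch3, "biom", standardize = FALSE)
  ll3 <- vapply(grid, cox_partial_loglik, numeric(1),
                entry = ch3$age_baseline, exit = ch3$age_at_event_or_censor,
                event = ch3$event_new_onset, x = ch3$biom)
  expect_equal(log(tidy(f3)$estimate), grid[which.max(ll3)], tolerance = 1e-3)
})

test_that("fits recover generator effects on a round trip", {
  cfg <- default_finrisk_config(
    n_subjects = 20000, seed = 17,
    prevalent_logit_coefs = c(intercept = -3.5, cert2 = 0.35),
    incident_log_hr_coefs = c(cert2 = log(1.16)))
  ch <- simulate_cohort(cfg)
  orp <- tidy(fit_prevalent(ch, "CERT2"))
  expect_true(orp$ci_low <= exp(0.35) && exp(0.35) <= orp$ci_high)
  hrp <- tidy(fit_new_onset(ch, "CERT2"))
  expect_true(hrp$ci_low <= 1.16 && 1.16 <= hrp$ci_high)
})

test_that("M1 is rejected for the age-timescale Cox analysis", {
  ch <- quick_cohort(300, 4)
  expect_error(fit_new_onset(ch, "CERT2", "M1"), "timescale")
})

test_that("degenerate survival data fail loudly", {
  ch <- make_cohort(30, event = FALSE)
  ch$biom <- rnorm(30)
  expect_error(fit_new_onset(ch, "biom", standardize = FALSE), "no new-onset events")
  ch2 <- make_cohort(10, event = c(TRUE, rep(FALSE, 9)))
  ch2$biom <- rnorm(10)
  ch2$age_at_event_or_censor[4] <- ch2$age_baseline[4]
  expect_error(fit_new_onset(ch2, "biom", standardize = FALSE), "H0004")
})

test_that("the association suite has the published layout", {
  ch <- quick_cohort(900, 6)
  res <- run_association_suite(ch, predictors = c("CERT1", "CERT2"))
  # 2 scores x (4 logistic + 3 Cox) models
  expect_equal(nrow(res), 14)
  expect_false(any(res$outcome == "new_onset" & res$model == "M1"))
  wide <- format_association_table(res)
  expect_equal(nrow(wide), 8)
  expect_true(all(res$ci_low <= res$estimate & res$estimate <= res$ci_high))
  expect_identical(res$significant, res$p_value < 0.05)

  lip <- run_association_suite(ch, predictors = lipid_predictors(),
                               outcomes = "prevalent")
  expect_equal(nrow(lip), 13 * 4)
  expect_true(all(lip$effect_type == "OR"))

  empty <- run_association_suite(ch, predictors = character(0))
  expect_equal(nrow(empty), 0)
  expect_error(run_association_suite(ch, predictors = "nosuch"),
               "valid names")
})

test_that("subject accounting balances in every fit", {
  ch <- quick_cohort(500, 11)
  ch$cer_18_0[c(5, 6)] <- NA
  f <- suppressMessages(fit_prevalent(ch, "cer_18_0", "M3"))
  g <- glance(f)
  expect_equal(g$n_used + g$n_excluded, 500L)
  prev_n <- sum(classify_prevalent(ch$sbp, ch$dbp, ch$bp_lowering_tx))
  fc <- suppressMessages(fit_new_onset(ch, "cer_18_0", "M2"))
  gc <- glance(fc)
  expect_equal(gc$n_used + gc$n_excluded, 500L - prev_n)
})

test_that("sex-stratified refits and interaction terms are available", {
  ch <- quick_cohort(1200, 13)
  res <- run_association_suite(ch, predictors = "CERT2",
                               outcomes = "prevalent", models = "unadjusted",
                               sex_analyses = TRUE)
  expect_setequal(res$analysis, c("main", "male", "female", "sex_interaction"))
  expect_equal(nrow(res), 4)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})
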