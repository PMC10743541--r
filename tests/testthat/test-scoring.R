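test_that("component values are ratios or raw concentrations", {
  prof <- tibble::tibble(cer_18_0 = 0.50, cer_16_0 = 0.25, cer_24_1 = 0.9,
                         cer_24_0 = 0.3, pc_16_0_16_0 = 1.3)
  ratio <- tibble::tibble(component = "r", numerator = "cer_18_0",
                          denominator = "cer_16_0")
  expect_equal(component_value(prof, ratio), 2.0)
  conc <- tibble::tibble(component = "c", numerator = "pc_16_0_16_0",
                         denominator = NA_character_)
  expect_equal(component_value(prof, conc), 1.3)
  ratio2 <- tibble::tibble(component = "r2", numerator = "cer_24_1",
                           denominator = "cer_24_0")
  expect_equal(component_value(prof, ratio2), 3.0)

  prof$subject_id <- "S1"
  prof$cer_16_0 <- 0
  expect_error(component_value(prof, ratio), "S1")
  expect_error(component_value(prof, ratio), "cer_16_0")
})

test_that("quartile cuts follow the linear-interpolation convention", {
  b <- fit_quartiles(1:8, "demo")
  expect_equal(c(b$q25, b$q50, b$q75), quantile_oracle(1:8, c(.25, .5, .75)))
  expect_equal(c(b$q25, b$q50, b$q75), c(2.75, 4.5, 6.25))
  b5 <- fit_quartiles(1:5, "demo")
  expect_equal(c(b5$q25, b5$q50, b5$q75), c(2, 3, 4))
  expect_false(b$degenerate)
  expect_equal(b$source, "cohort_internal")

  expect_warning(bc <- fit_quartiles(rep(7, 10), "const"), "degenerate")
  expect_equal(c(bc$q25, bc$q50, bc$q75), c(7, 7, 7))
  expect_true(bc$degenerate)

  expect_error(fit_quartiles(1:3, "few"), "at least 4")
})

test_that("points follow quartile membership with lower-closed cuts", {
  bounds <- tibble::tibble(component = "demo", q25 = 2.75, q50 = 4.5,
                           q75 = 6.25, source = "cohort_internal",
                           degenerate = FALSE)
  cert1_map <- cert_components("CERT1")[1, ]
  cert2_map <- cert_components("CERT2")[1, ]
  expect_equal(assign_points(2, bounds, cert1_map), 0L)
  expect_equal(assign_points(5, bounds, cert1_map), 1L)
  expect_equal(assign_points(7, bounds, cert2_map), 3L)
  # a value exactly on a cut belongs to the lower quartile
  expect_equal(assign_points(2.75, bounds, cert1_map), 0L)
  expect_equal(assign_points(4.5, bounds, cert2_map), 1L)
  expect_error(assign_points(NaN, bounds, cert1_map), "non-finite")
})

test_that("score definitions are structurally 0-12", {
  c1 <- cert_components("CERT1")
  c2 <- cert_components("CERT2")
  expect_equal(nrow(c1), 6)
  expect_equal(nrow(c2), 4)
  expect_true(all(c1$q4 == 2))
  expect_true(all(c2$q4 == 3))
  expect_equal(max_score(c1), 12L)
  expect_equal(max_score(c2), 12L)
})

test_that("extreme subjects reach the score floor and ceiling", {
  ch <- quick_cohort(200, 3)
  hi <- lo <- ch[1, ]
  hi[, c("cer_16_0", "cer_18_0", "cer_24_1", "pc_16_0_16_0")] <- 1e4
  hi[, c("cer_24_0", "pc_14_0_22_6", "pc_16_0_22_5")] <- 1e-4
  lo[, c("cer_16_0", "cer_18_0", "cer_24_1", "pc_16_0_16_0")] <- 1e-4
  lo[, c("cer_24_0", "pc_14_0_22_6", "pc_16_0_22_5")] <- 1e4
  hi$subject_id <- "HI"; lo$subject_id <- "LO"
  aug <- dplyr::bind_rows(ch, hi, lo)
  for (s in c("CERT1", "CERT2")) {
    sc <- score_cohort(aug, s)
    expect_equal(sc$total[sc$subject_id == "HI"], 12L)
    expect_equal(sc$total[sc$subject_id == "LO"], 0L)
    expect_equal(as.character(sc$category[sc$subject_id == "HI"]), "high")
    expect_equal(as.character(sc$category[sc$subject_id == "LO"]), "low")
  }
})

test_that("on tie-free data each quartile holds n/4 subjects", {
  ch <- quick_cohort(1000, 5)
  for (s in c("CERT1", "CERT2")) {
    sc <- score_cohort(ch, s)
    comps <- cert_components(s)$component
    b <- attr(sc, "boundaries")
    for (comp in comps) {
      v <- sc[[paste0("value_", comp)]]
      cuts <- b[b$component == comp, ]
      occ <- c(sum(v <= cuts$q25), sum(v > cuts$q25 & v <= cuts$q50),
               sum(v > cuts$q50 & v <= cuts$q75), sum(v > cuts$q75))
      expect_true(all(abs(occ - 250) <= 1))
      expect_equal(sum(v > cuts$q75), 250)
    }
  }
})

test_that("totals stay in 0-12 and increasing a component never lowers a score", {
  for (seed in 1:3) {
    ch <- quick_cohort(250, seed)
    sc <- score_cohort(ch, "CERT2")
    expect_true(all(sc$total >= 0 & sc$total <= 12))
    b <- attr(sc, "boundaries")
    bumped <- ch
    bumped$cer_24_1 <- bumped$cer_24_1 * ifelse(seq_len(nrow(ch)) == 10, 3, 1)
    sc2 <- score_cohort(bumped, "CERT2", boundaries = b)
    expect_gte(sc2$total[10], sc$total[10])
    expect_equal(sc2$total[-10], sc$total[-10])
  }
})

test_that("scores are invariant to cohort row order", {
  ch <- quick_cohort(300, 7)
  sc <- score_cohort(ch, "CERT1")
  perm <- sample(nrow(ch))
  scp <- score_cohort(ch[perm, ], "CERT1")
  merged <- dplyr::left_join(as.data.frame(sc)[, c("subject_id", "total")],
                             as.data.frame(scp)[, c("subject_id", "total")],
                             by = "subject_id")
  expect_equal(merged$total.x, merged$total.y)
})

test_that("subjects with missing lipids are excluded with a reported count", {
  ch <- quick_cohort(100, 2)
  ch$cer_18_0[c(3, 50, 71)] <- NA
  expect_message(sc <- score_cohort(ch, "CERT1"), "excluded 3 of 100")
  expect_equal(nrow(sc), 97)
  expect_equal(attr(sc, "n_excluded"), 3)
})

test_that("frozen external boundaries are honoured", {
  ch <- quick_cohort(120, 8)
  sc <- score_cohort(ch, "CERT2")
  b <- attr(sc, "boundaries")
  b$source <- "external_reference"
  other <- quick_cohort(120, 9)
  sc2 <- score_cohort(other, "CERT2", boundaries = b)
  expect_identical(attr(sc2, "boundaries")$source, rep("external_reference", 4))
  # scoring one row against frozen cuts is well defined
  one <- score_cohort(other[1, ], "CERT2", boundaries = b)
  expect_equal(nrow(one), 1)
})
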