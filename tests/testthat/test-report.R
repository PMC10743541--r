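test_that("cohort TSV round trip preserves every field type", {
  ch <- quick_cohort(150, 21)
  ch$crp[c(4, 9)] <- NA
  ch$smoking[7] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(ch, path)
  back <- read_cohort(path)
  expect_equal(back, ch, ignore_attr = TRUE)
})

test_that("schema and row-level errors are reported precisely", {
  ch <- quick_cohort(20, 22)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(ch, path)

  txt <- readLines(path)
  hdr <- strsplit(txt[1], "\t")[[1]]
  drop <- which(hdr == "dbp")
  trunc <- vapply(txt, function(l) {
    paste(strsplit(l, "\t")[[1]][-drop], collapse = "\t")
  }, character(1))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(trunc, path2)
  expect_error(read_cohort(path2), "dbp")

  bad <- txt
  fields <- strsplit(bad[6], "\t")[[1]]
  fields[which(hdr == "cer_16_0")] <- "oops"
  bad[6] <- paste(fields, collapse = "\t")
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(bad, path3)
  expect_error(read_cohort(path3, on_error = "error"), "line 6")
  expect_message(skipped <- read_cohort(path3, on_error = "skip"), "1 malformed")
  expect_equal(nrow(skipped), 19)
  expect_equal(attr(skipped, "n_skipped"), 1L)
})

test_that("a column map adapts foreign headers", {
  ch <- quick_cohort(15, 23)
  path <- withr::local_tempfile(fileext = ".tsv")
  tmp <- dplyr::rename(ch, systolic = sbp)
  readr::write_tsv(tmp, path, na = "")
  back <- read_cohort(path, column_map = c(sbp = "systolic"))
  expect_equal(back$sbp, ch$sbp)
  expect_error(read_cohort(path, column_map = c(sbp = "nope")), "nope")
})

test_that("baseline percentages reproduce the published arithmetic", {
  n_free <- 6847; n_prev <- 875
  ch <- make_cohort(n_free + n_prev,
                    sbp = c(rep(120, n_free), rep(150, n_prev)),
                    sex = c(rep("male", 3157), rep("female", n_free - 3157),
                            rep("male", 462), rep("female", n_prev - 462)),
                    died = c(rep(FALSE, n_free),
                             rep(TRUE, 217), rep(FALSE, n_prev - 217)))
  tab <- suppressWarnings(baseline_table(ch, "prevalent_status",
                                         include_scores = FALSE))
  men <- tab[tab$variable == "Men n (%)", ]
  expect_equal(men$pct[men$group == "no_hypertension"], 46.1)
  expect_equal(men$formatted[men$group == "no_hypertension"], "3157 (46.1%)")
  death <- tab[tab$variable == "Death during the follow-up", ]
  expect_equal(death$pct[death$group == "hypertension"], 24.8)
  expect_equal(death$count[death$group == "hypertension"], 217L)
  expect_equal(sum(attr(tab, "group_sizes")), 7722L)
  # percentages re-derivable from emitted counts to one decimal exactly
  cat_rows <- tab[tab$type == "categorical", ]
  expect_equal(cat_rows$pct, round(100 * cat_rows$count / cat_rows$group_n, 1))
})

test_that("absent categories are reported as zero and empty groups fail", {
  ch <- make_cohort(40, sbp = c(rep(120, 30), rep(150, 10)))
  tab <- baseline_table(ch, "prevalent_status", include_scores = FALSE)
  smk <- tab[tab$variable == "Current smoking", ]
  expect_equal(smk$formatted, c("0 (0.0%)", "0 (0.0%)"))
  all_free <- make_cohort(30, sbp = 120)
  expect_error(baseline_table(all_free, "prevalent_status"), "hypertension")
})

test_that("the pipeline is deterministic and honours configuration scope", {
  cfg <- list(seed = 5,
              cohort = list(source = "simulate", n_subjects = 500),
              scores = list("CERT1", "CERT2"),
              associations = list(enabled = TRUE,
                                  predictors = list("CERT1", "CERT2")),
              curves = list(list(predictor = "cer_18_0",
                                 outcome = "prevalent")),
              baseline_tables = list("prevalent_status"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, output_dir = d1)
  r2 <- run_pipeline(cfg, output_dir = d2)
  f1 <- sort(basename(r1$paths))
  expect_identical(f1, sort(basename(r2$paths)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  expect_identical(r1$manifest, r2$manifest)
  # manifest lists every emitted file with a hash
  listed <- vapply(r1$manifest$outputs, `[[`, "", "file")
  expect_setequal(c(listed, "manifest.json"), f1)

  wide <- readr::read_tsv(file.path(d1, "associations_wide.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(wide), 8)

  cfg2 <- cfg
  cfg2$scores <- list("CERT2")
  cfg2$associations$predictors <- list("CERT2")
  d3 <- withr::local_tempdir()
  r3 <- run_pipeline(cfg2, output_dir = d3)
  expect_false(any(grepl("CERT1", basename(r3$paths))))
  assoc <- readr::read_tsv(file.path(d3, "associations.tsv"),
                           show_col_types = FALSE)
  expect_false(any(assoc$predictor == "CERT1"))
})

test_that("a failing stage names itself and leaves no partial outputs", {
  cfg <- list(seed = 6, cohort = list(source = "simulate", n_subjects = 120),
              scores = list("CERT1"),
              associations = list(enabled = FALSE),
              curves = list(list(predictor = "not_a_lipid")))
  out <- file.path(withr::local_tempdir(), "run")
  expect_error(run_pipeline(cfg, output_dir = out), "curve_not_a_lipid")
  expect_false(dir.exists(out))
})
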