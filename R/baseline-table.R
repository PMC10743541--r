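#' Baseline-characteristics table
#'
#' Summarises the cohort the way epidemiological baseline tables do:
#' continuous variables as mean (SD) with a Welch two-sample t-test p-value,
#' categorical variables as n (%) with a Pearson chi-square p-value
#' (percentages as count / group-n x 100, one decimal). Groupings:
#' `prevalent_status` (hypertensive vs not at baseline, whole cohort),
#' `new_onset_status` (developed hypertension during follow-up vs not, among
#' the baseline hypertension-free) or `sex`.
#'
#' @param cohort Cohort tibble.
#' @param grouping One of `"prevalent_status"`, `"new_onset_status"`,
#'   `"sex"`.
#' @param include_scores Add CERT1/CERT2 rows (requires the lipid columns),
#'   default `TRUE`.
#' @return Long tibble: `variable`, `type`, `group`, `group_n`, `mean`,
#'   `sd`, `count`, `pct`, `formatted`, `p_value` (repeated within
#'   variable). Use [format_baseline_table()] for the wide layout.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_finrisk_config(n_subjects = 400, seed = 2))
#' tab <- baseline_table(cohort, "prevalent_status")
#' format_baseline_table(tab)
baseline_table <- function(cohort,
                           grouping = c("prevalent_status", "new_onset_status", "sex"),
                           include_scores = TRUE) {
  grouping <- match.arg(grouping)
  prevalent <- classify_prevalent(cohort$sbp, cohort$dbp, cohort$bp_lowering_tx)
  if (grouping == "prevalent_status") {
    dat <- cohort
    group <- ifelse(prevalent, "hypertension", "no_hypertension")
    levels <- c("no_hypertension", "hypertension")
  } else if (grouping == "new_onset_status") {
    dat <- cohort[!prevalent, , drop = FALSE]
    group <- ifelse(dat$event_new_onset, "new_onset", "no_new_onset")
    levels <- c("no_new_onset", "new_onset")
  } else {
    dat <- cohort
    group <- dat$sex
    levels <- c("female", "male")
  }
  group <- factor(group, levels = levels)
  empty <- levels[table(group)[levels] == 0]
  if (length(empty) > 0) {
    abort_cfg(paste0("empty group '", empty[1], "' for grouping ", grouping))
  }

  if (include_scores && all(lipid_species() %in% names(dat)) && nrow(dat) >= 4) {
    dat$cert1 <- suppressWarnings(score_cohort(dat, "CERT1"))$total
    dat$cert2 <- suppressWarnings(score_cohort(dat, "CERT2"))$total
  }

  continuous <- c(age_baseline = "Age (years)", bmi = "BMI (kg/m2)",
                  waist = "Waist circumference (cm)",
                  tg = "Serum triglycerides (mmol/L)",
                  tc = "Serum total cholesterol (mmol/L)",
                  hdl = "Serum HDL (mmol/L)", ldl = "Serum LDL (mmol/L)",
                  crp = "Serum CRP (mg/dL)", sbp = "Systolic BP (mmHg)",
                  dbp = "Diastolic BP (mmHg)", cert1 = "CERT1",
                  cert2 = "CERT2")
  categorical <- c(male = "Men n (%)", smoking = "Current smoking",
                   diabetes = "Diabetes mellitus",
                   lipid_lowering_tx = "Lipid-lowering drug treatment",
                   bp_lowering_tx = "BP-lowering drug treatment",
                   died = "Death during the follow-up")
  if (grouping == "sex") categorical <- categorical[names(categorical) != "male"]
  dat$male <- dat$sex == "male"

  rows <- list()
  for (v in names(continuous)) {
    if (!v %in% names(dat)) next
    rows[[length(rows) + 1]] <- baseline_row_continuous(dat[[v]], group,
                                                        continuous[[v]])
  }
  for (v in names(categorical)) {
    if (!v %in% names(dat)) next
    rows[[length(rows) + 1]] <- baseline_row_categorical(dat[[v]], group,
                                                         categorical[[v]])
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "grouping") <- grouping
  attr(out, "group_sizes") <- as.integer(table(group)[levels])
  out
}

baseline_row_continuous <- function(x, group, label) {
  p <- tryCatch(t.test(x ~ group)$p.value, error = function(e) NA_real_)
  lv <- levels(group)
  ns <- as.integer(table(group)[lv])
  means <- vapply(split(x, group)[lv], mean, 0, na.rm = TRUE)
  sds <- vapply(split(x, group)[lv], sd, 0, na.rm = TRUE)
  tibble::tibble(
    variable = label, type = "continuous", group = lv, group_n = ns,
    mean = unname(means), sd = unname(sds),
    count = NA_integer_, pct = NA_real_,
    formatted = sprintf("%.1f (%.1f)", means, sds),
    p_value = p
  )
}

baseline_row_categorical <- function(x, group, label) {
  x <- as.logical(x)
  lv <- levels(group)
  counts <- as.integer(vapply(split(x, group)[lv], sum, 0, na.rm = TRUE))
  ns <- as.integer(table(group)[lv])
  pct <- round(100 * counts / ns, 1)
  p <- tryCatch({
    tab <- table(group, x)
    if (ncol(tab) < 2) NA_real_ else
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }, error = function(e) NA_real_)
  tibble::tibble(
    variable = label, type = "categorical", group = lv,
    group_n = ns, mean = NA_real_, sd = NA_real_,
    count = counts, pct = pct,
    formatted = sprintf("%d (%.1f%%)", counts, pct),
    p_value = p
  )
}

#' Wide layout for a baseline table
#'
#' @param table Output of [baseline_table()].
#' @return Tibble with one row per variable, one formatted column per group,
#'   and the between-group p-value.
#' @export
format_baseline_table <- function(table) {
  wide <- tidyr::pivot_wider(
    dplyr::select(table, dplyr::all_of(c("variable", "group", "formatted", "p_value"))),
    names_from = "group", values_from = "formatted")
  dplyr::relocate(wide, "p_value", .after = dplyr::last_col())
}
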