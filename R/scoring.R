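#' Component definitions for the CERT scores
#'
#' CERT1 has six components: the concentrations of Cer(d18:1/16:0),
#' Cer(d18:1/18:0) and Cer(d18:1/24:1), and the same three species as ratios
#' to Cer(d18:1/24:0). Each component awards 0/0/1/2 points for quartiles
#' Q1..Q4, so the total runs 0-12. CERT2 has four components --
#' Cer(d18:1/24:1)/Cer(d18:1/24:0), Cer(d18:1/16:0)/PC(16:0/22:5),
#' Cer(d18:1/18:0)/PC(14:0/22:6) and the PC(16:0/16:0) concentration -- each
#' awarding 0/1/2/3 points, so the total is again 0-12.
#'
#' @param score `"CERT1"` or `"CERT2"`.
#' @return A tibble with one row per component: `component`, `numerator`,
#'   `denominator` (`NA` for a raw concentration) and the quartile point map
#'   `q1`..`q4`.
#' @export
#' @examples
#' cert_components("CERT2")
cert_components <- function(score = c("CERT1", "CERT2")) {
  score <- match.arg(score)
  if (score == "CERT1") {
    spec <- tibble::tibble(
      component = c("cer_16_0", "cer_18_0", "cer_24_1",
                    "cer_16_0_by_cer_24_0", "cer_18_0_by_cer_24_0",
                    "cer_24_1_by_cer_24_0"),
      numerator = c("cer_16_0", "cer_18_0", "cer_24_1",
                    "cer_16_0", "cer_18_0", "cer_24_1"),
      denominator = c(NA, NA, NA, "cer_24_0", "cer_24_0", "cer_24_0"),
      q1 = 0L, q2 = 0L, q3 = 1L, q4 = 2L
    )
  } else {
    spec <- tibble::tibble(
      component = c("cer_24_1_by_cer_24_0", "cer_16_0_by_pc_16_0_22_5",
                    "cer_18_0_by_pc_14_0_22_6", "pc_16_0_16_0"),
      numerator = c("cer_24_1", "cer_16_0", "cer_18_0", "pc_16_0_16_0"),
      denominator = c("cer_24_0", "pc_16_0_22_5", "pc_14_0_22_6", NA),
      q1 = 0L, q2 = 1L, q3 = 2L, q4 = 3L
    )
  }
  validate_components(spec)
  spec
}

validate_components <- function(spec) {
  pts <- as.matrix(spec[, c("q1", "q2", "q3", "q4")])
  if (any(pts < 0)) abort_cfg("component point maps must be non-negative")
  if (any(t(apply(pts, 1, diff)) < 0)) {
    abort_cfg("component point maps must be non-decreasing from Q1 to Q4")
  }
  same <- !is.na(spec$denominator) & spec$numerator == spec$denominator
  if (any(same)) {
    abort_cfg(sprintf("component '%s' has identical numerator and denominator",
                      spec$component[same][1]))
  }
  invisible(spec)
}

#' Value of one score component for one or more lipid profiles
#'
#' Returns the numerator/denominator ratio, or the raw numerator
#' concentration when the component has no denominator.
#'
#' @param profile A data frame with the [lipid_species()] columns (one row per
#'   subject), or a named list/vector for a single subject.
#' @param spec One row of [cert_components()] (or any data frame with
#'   `component`, `numerator`, `denominator`).
#' @return Numeric vector of component values, one per profile row.
#' @export
#' @examples
#' component_value(
#'   data.frame(cer_18_0 = 0.5, cer_16_0 = 0.25),
#'   data.frame(component = "r", numerator = "cer_18_0", denominator = "cer_16_0")
#' )
component_value <- function(profile, spec) {
  if (!is.data.frame(profile)) profile <- tibble::as_tibble(as.list(profile))
  stopifnot(nrow(spec) == 1)
  num <- profile[[spec$numerator]]
  if (is.null(num)) {
    abort_cfg(sprintf("profile lacks lipid column '%s'", spec$numerator))
  }
  if (is.na(spec$denominator)) return(as.numeric(num))
  den <- profile[[spec$denominator]]
  if (is.null(den)) {
    abort_cfg(sprintf("profile lacks lipid column '%s'", spec$denominator))
  }
  bad <- which(!is.na(den) & den <= 0)
  if (length(bad) > 0) {
    id <- if (!is.null(profile$subject_id)) profile$subject_id[bad[1]] else bad[1]
    stop(sprintf("non-positive denominator '%s' for component '%s' (subject %s)",
                 spec$denominator, spec$component, id), call. = FALSE)
  }
  as.numeric(num) / as.numeric(den)
}

# All component values for a cohort: tibble n x components.
component_values <- function(cohort, components) {
  out <- purrr::map(seq_len(nrow(components)), function(i) {
    component_value(cohort, components[i, ])
  })
  names(out) <- components$component
  tibble::as_tibble(out)
}

#' Quartile boundaries for one score component
#'
#' Cut points are the 25th/50th/75th percentiles under the linear
#' interpolation convention ([stats::quantile()] `type = 7`). Values falling
#' exactly on a cut belong to the lower quartile.
#'
#' @param values Numeric vector (at least 4 finite values).
#' @param component_name Label recorded in the result.
#' @param quantile_type Passed to [stats::quantile()]; default 7.
#' @return One-row tibble: `component`, `q25`, `q50`, `q75`, `source`
#'   (`"cohort_internal"`) and `degenerate` (`TRUE` when ties collapse the
#'   cuts).
#' @export
#' @examples
#' fit_quartiles(1:8, "demo") # cuts 2.75 / 4.5 / 6.25
fit_quartiles <- function(values, component_name = "component",
                          quantile_type = 7) {
  values <- values[is.finite(values)]
  if (length(values) < 4) {
    stop(sprintf("need at least 4 finite values to place quartiles for '%s' (got %d)",
                 component_name, length(values)), call. = FALSE)
  }
  cuts <- unname(quantile(values, c(0.25, 0.5, 0.75), type = quantile_type))
  degen <- any(duplicated(cuts))
  if (degen) {
    warning(sprintf("degenerate quartile cuts for '%s': ties collapse one or more cut points",
                    component_name), call. = FALSE)
  }
  tibble::tibble(component = component_name, q25 = cuts[1], q50 = cuts[2],
                 q75 = cuts[3], source = "cohort_internal", degenerate = degen)
}

#' Quartile points for component values
#'
#' Quartile membership uses the intervals (-Inf, q25], (q25, q50], (q50, q75],
#' (q75, Inf); the returned points are the component's Q1..Q4 map entries.
#'
#' @param value Numeric vector of component values.
#' @param bounds One-row boundaries tibble (see [fit_quartiles()]); an
#'   `external_reference` row with fixed published cuts works identically.
#' @param spec One row of [cert_components()] supplying the point map.
#' @return Integer points, one per value.
#' @export
assign_points <- function(value, bounds, spec) {
  stopifnot(nrow(bounds) == 1, nrow(spec) == 1)
  if (any(!is.finite(value))) {
    stop(sprintf("non-finite component value for '%s'", spec$component),
         call. = FALSE)
  }
  quart <- 1L + (value > bounds$q25) + (value > bounds$q50) + (value > bounds$q75)
  map <- c(spec$q1, spec$q2, spec$q3, spec$q4)
  as.integer(map[quart])
}

#' Risk-category bands for a CERT score
#'
#' Totals 0-12 are partitioned into low / moderate / increased / high CVD
#' risk. Default bands: CERT1 0-2 / 3-6 / 7-9 / 10-12 and CERT2 0-3 / 4-6 /
#' 7-8 / 9-12 (taken from the published score literature; configurable).
#'
#' @param score `"CERT1"` or `"CERT2"`.
#' @return List with `score` and `upper` (the three integer upper bounds of
#'   the first three bands).
#' @export
default_category_scheme <- function(score = c("CERT1", "CERT2")) {
  score <- match.arg(score)
  upper <- if (score == "CERT1") c(2L, 6L, 9L) else c(3L, 6L, 8L)
  list(score = score, upper = upper)
}

category_labels <- function() c("low", "moderate", "increased", "high")

score_category <- function(total, scheme) {
  u <- scheme$upper
  if (length(u) != 3 || any(diff(u) <= 0) || any(u < 0) || any(u > 12)) {
    abort_cfg("category scheme must give three strictly increasing bounds in [0, 12]")
  }
  cut(total, breaks = c(-1L, u, 12L), labels = category_labels())
}

#' Score a cohort with CERT1 or CERT2
#'
#' Computes every component value, places quartile boundaries once on the
#' whole input cohort (unless frozen external boundaries are supplied),
#' assigns quartile points and sums them into the 0-12 total with its risk
#' category. Subjects missing any required lipid are dropped (complete-case)
#' with a reported count.
#'
#' @param cohort Data frame with the [lipid_species()] columns (and optionally
#'   `subject_id`).
#' @param score `"CERT1"` or `"CERT2"`.
#' @param components Component table; defaults to [cert_components()] for
#'   `score`.
#' @param boundaries Optional boundaries tibble (one row per component, as
#'   from [fit_quartiles()]) to use as frozen external reference cuts; when
#'   `NULL` (default) quartiles are fitted on `cohort` itself.
#' @param categories Category scheme; defaults to
#'   [default_category_scheme()] for `score`.
#' @param quantile_type Quantile convention for cohort-internal boundaries.
#' @return Tibble with `subject_id`, `score`, one `value_*` and `points_*`
#'   column per component, `total` and `category`. Attributes: `boundaries`
#'   (audit table) and `n_excluded`.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_finrisk_config(n_subjects = 200, seed = 1))
#' scores <- score_cohort(cohort, "CERT2")
#' table(scores$category)
score_cohort <- function(cohort, score = c("CERT1", "CERT2"),
                         components = NULL, boundaries = NULL,
                         categories = NULL, quantile_type = 7) {
  score <- match.arg(score)
  components <- components %||% cert_components(score)
  validate_components(components)
  categories <- categories %||% default_category_scheme(score)

  needed <- unique(c(components$numerator,
                     components$denominator[!is.na(components$denominator)]))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    abort_cfg(paste0("cohort lacks lipid column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  if (is.null(cohort$subject_id)) {
    cohort$subject_id <- sprintf("row%05d", seq_len(nrow(cohort)))
  }

  complete <- complete.cases(cohort[needed])
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(sprintf("score_cohort: excluded %d of %d subjects with missing lipid values",
                    n_excluded, nrow(cohort)))
  }
  used <- cohort[complete, , drop = FALSE]
  vals <- component_values(used, components)

  if (is.null(boundaries)) {
    boundaries <- purrr::map_dfr(seq_len(nrow(components)), function(i) {
      fit_quartiles(vals[[components$component[i]]], components$component[i],
                    quantile_type = quantile_type)
    })
  } else {
    if (!all(components$component %in% boundaries$component)) {
      abort_cfg("supplied boundaries do not cover every score component")
    }
    boundaries$source <- boundaries$source %||% "external_reference"
  }

  pts <- purrr::map(seq_len(nrow(components)), function(i) {
    comp <- components$component[i]
    assign_points(vals[[comp]], boundaries[boundaries$component == comp, ],
                  components[i, ])
  })
  names(pts) <- components$component
  pts <- tibble::as_tibble(pts)

  total <- as.integer(rowSums(pts))
  out <- tibble::tibble(subject_id = used$subject_id, score = score)
  names(vals) <- paste0("value_", names(vals))
  names(pts) <- paste0("points_", names(pts))
  out <- dplyr::bind_cols(out, vals, pts)
  out$total <- total
  out$category <- score_category(total, categories)
  attr(out, "boundaries") <- boundaries
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("cert_scores", class(out))
  out
}

#' Maximum attainable total of a score definition
#'
#' Structural check: summing each component's Q4 points. Both default scores
#' reach 12 (CERT1: 6 components x 2; CERT2: 4 components x 3).
#'
#' @param components A component table, e.g. [cert_components()].
#' @return Integer maximum total.
#' @export
max_score <- function(components) {
  validate_components(components)
  as.integer(sum(components$q4))
}
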