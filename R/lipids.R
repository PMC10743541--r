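#' Lipid species measured by the panel
#'
#' The scoring system uses seven lipid species: four ceramides --
#' Cer(d18:1/16:0), Cer(d18:1/18:0), Cer(d18:1/24:0), Cer(d18:1/24:1) -- and
#' three phosphatidylcholines -- PC(14:0/22:6), PC(16:0/22:5), PC(16:0/16:0).
#' These names are also the cohort column names holding the concentrations
#' (one common, strictly positive unit).
#'
#' @return Character vector of the seven column names.
#' @export
#' @examples
#' lipid_species()
lipid_species <- function() {
  c("cer_16_0", "cer_18_0", "cer_24_0", "cer_24_1",
    "pc_14_0_22_6", "pc_16_0_22_5", "pc_16_0_16_0")
}

# Pretty labels for plots and reports.
lipid_label <- function(x) {
  lab <- c(
    cer_16_0 = "Cer(d18:1/16:0)", cer_18_0 = "Cer(d18:1/18:0)",
    cer_24_0 = "Cer(d18:1/24:0)", cer_24_1 = "Cer(d18:1/24:1)",
    pc_14_0_22_6 = "PC(14:0/22:6)", pc_16_0_22_5 = "PC(16:0/22:5)",
    pc_16_0_16_0 = "PC(16:0/16:0)"
  )
  vapply(strsplit(x, "_by_"), function(parts) {
    paste(lab[parts], collapse = " / ")
  }, character(1))
}

#' The thirteen lipid predictors of the association suite
#'
#' Seven raw species plus the six concentration ratios analysed alongside the
#' CERT scores: the three CERT1 ratios to Cer(d18:1/24:0), the two CERT2
#' ceramide/PC ratios, and Cer(d18:1/18:0)/Cer(d18:1/16:0). Ratio names are
#' `<numerator>_by_<denominator>`.
#'
#' @return Character vector of 13 predictor names.
#' @export
lipid_predictors <- function() {
  c(lipid_species(),
    "cer_16_0_by_cer_24_0", "cer_18_0_by_cer_24_0", "cer_24_1_by_cer_24_0",
    "cer_16_0_by_pc_16_0_22_5", "cer_18_0_by_pc_14_0_22_6",
    "cer_18_0_by_cer_16_0")
}

# Split a predictor name into numerator/denominator (denominator NA for a raw
# concentration).
parse_lipid_predictor <- function(name) {
  parts <- strsplit(name, "_by_", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    list(numerator = parts[1], denominator = NA_character_)
  } else {
    list(numerator = parts[1], denominator = parts[2])
  }
}
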