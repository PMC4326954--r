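# Worked example: the reference 12-feature blood/body panel ------------------
#
# The package ships a synthetic *encoding* of the evidence behind the
# canonical 12-feature result panel (B cells, lymphocytes, red cells,
# haemoglobin, hematocrit, magnesium, neutrophils, iron, CHr, thyroxine,
# BMI, heart rate): per-sex/per-age prognostic correlation directions with
# their qualifier structure, per-sex trend directions, and the literature
# effect valences.  The numeric magnitudes are illustrative stand-ins (the
# underlying phenotype measurements are external); the directions, relative
# strengths and qualifier patterns are what the engine consumes.

#' Load the packaged 12-feature evidence encoding
#'
#' @return named list of evidence bundles (see [build_evidence()]) for the
#'   12 canonical features
#' @export
example_panel_bundles <- function() {
  ext <- function(f) system.file("extdata", f, package = "agemarkers",
                                 mustWork = TRUE)
  cells <- read.csv(ext("example_panel_prognostic.csv"), stringsAsFactors = FALSE)
  cells$n <- NA_integer_
  cells$relevant <- abs(cells$pearson_r) >= 0.2 & cells$p_value < 0.05
  cells$degenerate <- FALSE
  trends <- read.csv(ext("example_panel_trends.csv"), stringsAsFactors = FALSE)
  trends$r_longitudinal <- sign(trends$slope_m)
  trends$n <- NA_integer_
  trends$trend_call <- ifelse(trends$p_value >= 0.05, "none",
                              ifelse(trends$slope_m < 0, "down", "up"))
  ann <- read_annotations(ext("example_panel_annotations.csv"))
  build_evidence(trends, cells, ann)
}

#' Expected classification of the 12-feature worked example
#'
#' @return data.frame feature / overall class, the reference panel result:
#'   six pro-longevity features, one antilongevity feature, five
#'   role-switching features
#' @export
example_panel_expected <- function() {
  data.frame(
    feature = c("Bcells", "LYMPH", "RBC", "HGB", "HCT", "Mg", "NEUT",
                "Fe", "CHr", "T4", "BMI", "HR"),
    overall = c(rep("pro_longevity", 6), "antilongevity",
                rep("role_switching", 5)),
    stringsAsFactors = FALSE)
}
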