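# Packaged per-patient fixture tables (demographics, morphology,
# plaque-level biomechanics, site-level comparisons) with a checksum
# guard against silent edits.

fixture_files <- c(
  table1_patients = "table1_patients.csv",
  table5_morphology = "table5_morphology.csv",
  table6_biomech = "table6_biomech.csv",
  table7_site_fss = "table7_site_fss.csv",
  table8_site_pws = "table8_site_pws.csv"
)

# md5 checksums of the shipped transcriptions (set at packaging time)
fixture_md5 <- c(
  table1_patients = "ae913099fda74593f2f3ce82307dcd8a",
  table5_morphology = "d077a8f84fe4373afac54cb844200c0c",
  table6_biomech = "18cf78b5cda7cfe06908dc6d70346748",
  table7_site_fss = "0a733bd834b60a06f451e0b957f356c3",
  table8_site_pws = "7602bb7c066cbf35b16214b7d1eeda99"
)

#' Load a packaged per-patient fixture table
#'
#' Fixture names: `table1_patients` (demographics and blood pressure),
#' `table5_morphology` (cap thickness, area stenosis, plaque burden),
#' `table6_biomech` (plaque-level PWS/PWSn/FSS), `table7_site_fss` and
#' `table8_site_pws` (erosion-site vs non-site comparisons for the eight
#' eroded plaques). Units are carried in the column names.
#'
#' @param name Fixture name.
#' @return Typed tibble with patient identifiers P1-P16 preserved.
#' @export
load_fixture <- function(name) {
  if (!name %in% names(fixture_files)) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(fixture_files), collapse = ", ")), call. = FALSE)
  }
  path <- system.file("extdata", fixture_files[[name]], package = "plaquemech")
  if (!nzchar(path)) stop("fixture file not found in the installed package", call. = FALSE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, fixture_md5[[name]])) {
    stop(sprintf("fixture '%s' failed its checksum (%s); the shipped transcription was modified",
                 name, md5), call. = FALSE)
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Merged per-patient predictor table from the fixtures
#'
#' Joins the morphology and biomechanics fixtures into one row per
#' patient with the predictors available from the printed tables (10 of
#' the 13: per-patient dFSS values and mean lumen area are not
#' published), plus `min_fss_dyn_cm2` and the erosion label. Percent
#' columns are converted to fractions.
#'
#' @return Tibble with 16 rows.
#' @export
fixture_predictor_table <- function() {
  m <- load_fixture("table5_morphology")
  b <- load_fixture("table6_biomech")
  dplyr::inner_join(b, dplyr::select(m, -"label"), by = "patient_id") |>
    dplyr::mutate(
      area_stenosis = .data$area_stenosis_pct / 100,
      mean_plaque_burden = .data$mean_plaque_burden_pct / 100
    ) |>
    dplyr::select(-"area_stenosis_pct", -"mean_plaque_burden_pct")
}

#' Predictors available in the fixture table
#'
#' The printed tables carry 10 of the 13 predictors (no per-patient dFSS,
#' no mean lumen area; minimum FSS is reported in comparisons but is not
#' a predictor).
#'
#' @return Character vector of 10 names.
#' @export
fixture_predictors <- function() {
  setdiff(erosion_predictors(),
          c("max_dfss_dyn_cm2", "mean_dfss_dyn_cm2", "mean_lumen_area_mm2"))
}
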