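# End-to-end orchestration: fixture-based or synthetic analysis runs
# producing the three analyses (plaque-level comparison, site-level
# comparison, prediction) as one report bundle.

#' Run the mechanics chain on one synthetic contour patient
#'
#' Generates a contour patient, removes any thrombus, preshrinks to the
#' zero-load state at the patient's mean pressure, evaluates the
#' structural and flow surrogates at the pressure extremes, and
#' aggregates to one predictor-table row.
#'
#' @param label "erosion" or "no_erosion".
#' @param seed Integer seed.
#' @param n_slices Slices in the stack.
#' @param stenosis_target Target area stenosis.
#' @param systolic,diastolic Blood pressure, mmHg.
#' @param preshrink Run the circumferential preshrink (slower); if FALSE
#'   the in vivo geometry is used as the zero-load state.
#' @return List with `patient`, `field`, `morphology`, `row` (the
#'   aggregated predictor row).
#' @export
simulate_contour_mechanics <- function(label, seed, n_slices = 8,
                                       stenosis_target = 0.5, systolic = 120,
                                       diastolic = 80, preshrink = FALSE) {
  patient <- generate_contour_patient(label = label, seed = seed,
                                      n_slices = n_slices,
                                      stenosis_target = stenosis_target,
                                      systolic = systolic, diastolic = diastolic)
  geom <- patient$geometry
  geom$slices <- lapply(geom$slices, remove_thrombus)
  zero_load <- if (preshrink) {
    apply_preshrink(geom, pressure_kpa = mmhg_to_kpa((systolic + 2 * diastolic) / 3))
  } else NULL
  field <- evaluate_timepoints(geom, zero_load = zero_load,
                               waveform = patient$waveform)
  morph <- patient_morphology(geom)
  row <- aggregate_patient(field, morph, patient_id = patient$patient_id,
                           label = label)
  list(patient = patient, field = field, morphology = morph, row = row)
}

#' Run the full erosion analysis pipeline
#'
#' With `source = "fixture"`, loads the packaged per-patient tables and
#' computes the plaque-level group comparison, the erosion-site
#' comparisons, and the prediction ranking over the predictors the
#' fixtures carry. With `source = "synthetic"`, generates a predictor
#' cohort from `config` and runs the same statistics and prediction
#' stages; `contour_patients > 0` additionally runs the full
#' geometry/mechanics chain on that many synthetic contour patients per
#' group and reports their aggregated predictor rows.
#'
#' @param source `"fixture"` or `"synthetic"`.
#' @param config A [cohort_config()] for the synthetic source.
#' @param seed Seed for the prediction bootstrap (and the synthetic
#'   cohort when `config` is NULL).
#' @param n_boot Bootstrap replicates per model (default 100).
#' @param max_size Largest predictor subset (default 2 keeps routine runs
#'   brisk; pass 3 for the full enumeration).
#' @param correlation_screen Apply the Pearson screening rule to
#'   multi-predictor models.
#' @param top_n Number of top-ranked models kept in the report.
#' @param contour_patients Synthetic contour patients per group pushed
#'   through the mechanics stages (0 = skip).
#' @param n_slices Slices per contour patient.
#' @return A list of class `erosion_report`.
#' @export
run_erosion_pipeline <- function(source = c("fixture", "synthetic"), config = NULL,
                                 seed = 1, n_boot = 100, max_size = 2,
                                 correlation_screen = TRUE, top_n = 10,
                                 contour_patients = 0, n_slices = 8) {
  source <- match.arg(source)
  if (source == "fixture") {
    table <- fixture_predictor_table()
    predictors <- fixture_predictors()
    site_fss <- load_fixture("table7_site_fss") |>
      dplyr::group_by(.data$stat) |>
      dplyr::group_modify(~ summarize_site_table(.x)) |>
      dplyr::ungroup()
    site_pws <- load_fixture("table8_site_pws") |>
      dplyr::group_by(.data$quantity) |>
      dplyr::group_modify(~ summarize_site_table(.x)) |>
      dplyr::ungroup()
  } else {
    if (is.null(config)) config <- cohort_config(seed = seed)
    table <- generate_predictor_cohort(config)
    predictors <- erosion_predictors()
    site_fss <- NULL
    site_pws <- NULL
  }
  numeric_vars <- names(table)[vapply(table, is.numeric, logical(1))]
  summary <- group_summary(table, numeric_vars)
  specs <- enumerate_models(table, predictors = predictors, max_size = max_size,
                            correlation_screen = correlation_screen)
  ranking <- rank_models(table, specs, n_boot = n_boot, seed = seed)

  mech_rows <- NULL
  if (contour_patients > 0) {
    stenosis_targets <- c(erosion = 0.654, no_erosion = 0.495)
    mech_rows <- purrr::map_dfr(seq_len(2 * contour_patients), function(i) {
      label <- if (i <= contour_patients) "erosion" else "no_erosion"
      simulate_contour_mechanics(label = label, seed = seed + i,
                                 n_slices = n_slices,
                                 stenosis_target = stenosis_targets[[label]])$row
    })
  }

  structure(
    list(source = source, seed = seed, n_boot = n_boot,
         predictor_table = table,
         group_summary = summary,
         site_fss = site_fss, site_pws = site_pws,
         model_ranking = utils::head(ranking, top_n),
         mechanics_rows = mech_rows,
         package_version = as.character(utils::packageVersion("plaquemech"))),
    class = "erosion_report"
  )
}

#' @export
print.erosion_report <- function(x, ...) {
  cat(sprintf("<erosion_report> source %s, seed %d, %d patients\n",
              x$source, x$seed, nrow(x$predictor_table)))
  cat("\nGroup summary (eroded vs non-eroded):\n")
  print(as.data.frame(x$group_summary), digits = 4)
  if (!is.null(x$site_fss)) {
    cat("\nErosion-site FSS comparison:\n")
    print(as.data.frame(x$site_fss), digits = 4)
  }
  if (!is.null(x$site_pws)) {
    cat("\nErosion-site PWS/PWSn comparison:\n")
    print(as.data.frame(x$site_pws), digits = 4)
  }
  cat("\nTop prediction models (bootstrap AUC):\n")
  print(as.data.frame(dplyr::select(x$model_ranking, -"result")), digits = 3)
  invisible(x)
}

#' Write a report bundle to CSV files
#'
#' Emits `group_summary.csv`, `model_ranking.csv`, `predictor_table.csv`
#' and, when present, `site_fss.csv`, `site_pws.csv`,
#' `mechanics_rows.csv`, plus a `run_info.csv` with seed and package
#' version.
#'
#' @param report An `erosion_report`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "erosion_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$group_summary, file.path(dir, "group_summary.csv"))
  readr::write_csv(dplyr::select(report$model_ranking, -"result"),
                   file.path(dir, "model_ranking.csv"))
  readr::write_csv(report$predictor_table, file.path(dir, "predictor_table.csv"))
  if (!is.null(report$site_fss)) readr::write_csv(report$site_fss, file.path(dir, "site_fss.csv"))
  if (!is.null(report$site_pws)) readr::write_csv(report$site_pws, file.path(dir, "site_pws.csv"))
  if (!is.null(report$mechanics_rows)) {
    readr::write_csv(report$mechanics_rows, file.path(dir, "mechanics_rows.csv"))
  }
  readr::write_csv(
    tibble::tibble(source = report$source, seed = report$seed,
                   n_boot = report$n_boot, package_version = report$package_version),
    file.path(dir, "run_info.csv")
  )
  invisible(dir)
}
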