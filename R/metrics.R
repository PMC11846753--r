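# Per-patient predictor assembly, group comparison, and erosion-site
# comparison with relative differences.

#' Aggregate a biomechanical field into one predictor-table row
#'
#' Pools all slice x point values at the maximum-pressure time point for
#' the stress/strain/shear maxima, means and minima; dFSS aggregates over
#' pooled per-point `FSS(maxP) - FSS(minP)` values; morphology metrics are
#' attached as-is.
#'
#' @param field A `biomech_field` from [evaluate_timepoints()].
#' @param morphology One-row tibble from [patient_morphology()].
#' @param patient_id,label Identifier columns for the output row.
#' @return One-row tibble with the 13 predictors plus `min_fss_dyn_cm2`
#'   and `label`.
#' @export
aggregate_patient <- function(field, morphology, patient_id = "P", label = NA_character_) {
  stopifnot(is.data.frame(field), is.data.frame(morphology), nrow(morphology) == 1)
  counts <- dplyr::count(field, .data$slice_index, .data$time_point)
  if (length(unique(counts$n)) > 1) {
    bad <- unique(counts$slice_index[counts$n != max(counts$n)])
    stop(sprintf("slices with missing points: %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  at_max <- field[field$time_point == "maxP", ]
  d <- delta_fss(field)
  tibble::tibble(
    patient_id = patient_id,
    label = label,
    max_pws_kpa = max(at_max$pws_kpa),
    mean_pws_kpa = mean(at_max$pws_kpa),
    max_pwsn = max(at_max$pwsn),
    mean_pwsn = mean(at_max$pwsn),
    max_fss_dyn_cm2 = max(at_max$fss_dyn_cm2),
    mean_fss_dyn_cm2 = mean(at_max$fss_dyn_cm2),
    min_fss_dyn_cm2 = min(at_max$fss_dyn_cm2),
    max_dfss_dyn_cm2 = max(d$dfss_dyn_cm2),
    mean_dfss_dyn_cm2 = mean(d$dfss_dyn_cm2),
    mean_plaque_burden = morphology$mean_plaque_burden,
    area_stenosis = morphology$area_stenosis,
    min_cap_thickness_um = morphology$min_cap_thickness_um,
    mean_cap_thickness_um = morphology$mean_cap_thickness_um,
    mean_lumen_area_mm2 = morphology$mean_lumen_area_mm2
  )
}

#' Relative difference between eroded and non-eroded results
#'
#' `(with - without) / without * 100`, signed percent.
#'
#' @param with_erosion,without_erosion Numeric values (vectorized).
#' @return Signed percent.
#' @export
relative_difference <- function(with_erosion, without_erosion) {
  if (any(without_erosion == 0)) stop("zero denominator in relative difference", call. = FALSE)
  (with_erosion - without_erosion) / without_erosion * 100
}

#' Per-group mean, SD and relative differences of a predictor table
#'
#' @param table Tibble with a `label` column ("erosion"/"no_erosion") and
#'   numeric predictor columns.
#' @param variables Columns to summarize; default all numeric columns.
#' @return Tibble of class `group_summary` with one row per variable:
#'   `eroded_mean`, `eroded_sd`, `non_eroded_mean`, `non_eroded_sd`,
#'   `relative_difference_pct`, and Wilcoxon rank-sum `p_value`.
#' @export
group_summary <- function(table, variables = NULL) {
  stopifnot("label" %in% names(table))
  groups <- split(table, table$label == "erosion")
  er <- groups[["TRUE"]]; ne <- groups[["FALSE"]]
  if (is.null(er) || is.null(ne)) stop("both groups must be non-empty", call. = FALSE)
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  out <- purrr::map_dfr(variables, function(v) {
    xe <- er[[v]]; xn <- ne[[v]]
    sd_flag <- length(xe) < 2 || length(xn) < 2
    tibble::tibble(
      variable = v,
      eroded_mean = mean(xe),
      eroded_sd = if (length(xe) >= 2) stats::sd(xe) else NA_real_,
      non_eroded_mean = mean(xn),
      non_eroded_sd = if (length(xn) >= 2) stats::sd(xn) else NA_real_,
      relative_difference_pct = relative_difference(mean(xe), mean(xn)),
      p_value = wilcoxon_test(xe, xn, paired = FALSE)$p_value,
      sd_undefined = sd_flag
    )
  })
  class(out) <- c("group_summary", class(out))
  out
}

#' Site-level statistics for eroded patients
#'
#' Splits each eroded patient's lumen points into erosion-labeled and
#' unlabeled sets and computes max/mean/min of each quantity per site
#' class, with the per-patient percentage difference.
#'
#' @param point_data Tibble with columns `patient_id`, `quantity`,
#'   `value`, `erosion` (logical); one row per lumen point per quantity.
#' @return Tibble of class `site_summary`: per patient and quantity,
#'   `stat` (max/mean/min), `with_erosion`, `without_erosion`,
#'   `difference_pct`.
#' @export
site_compare <- function(point_data) {
  req <- c("patient_id", "quantity", "value", "erosion")
  stopifnot(all(req %in% names(point_data)))
  out <- point_data |>
    dplyr::group_by(.data$patient_id, .data$quantity) |>
    dplyr::group_modify(function(df, key) {
      if (!any(df$erosion)) stop(sprintf("patient %s has no erosion-labeled points", key$patient_id),
                                 call. = FALSE)
      if (all(df$erosion)) stop(sprintf("patient %s has no non-erosion points", key$patient_id),
                                call. = FALSE)
      w <- df$value[df$erosion]
      o <- df$value[!df$erosion]
      tibble::tibble(
        stat = c("max", "mean", "min"),
        with_erosion = c(max(w), mean(w), min(w)),
        without_erosion = c(max(o), mean(o), min(o))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(difference_pct = relative_difference(.data$with_erosion, .data$without_erosion))
  class(out) <- c("site_summary", class(out))
  out
}

#' Group-level summary of a site comparison table
#'
#' Averages per-patient site statistics (as in a printed site-comparison
#' table: one row per patient with "sites with erosion" and "sites
#' without erosion" columns) and runs the paired exact signed-rank test
#' across patients; the unpaired exact rank-sum test is reported
#' alongside.
#'
#' @param site_table Tibble with columns `patient_id`, `with_erosion`,
#'   `without_erosion` (one row per patient for a single quantity/stat).
#' @return One-row tibble: means, SDs, relative difference of the means,
#'   paired exact p, unpaired exact p.
#' @export
summarize_site_table <- function(site_table) {
  req <- c("patient_id", "with_erosion", "without_erosion")
  stopifnot(all(req %in% names(site_table)))
  w <- site_table$with_erosion
  o <- site_table$without_erosion
  tibble::tibble(
    n = length(w),
    with_mean = mean(w), with_sd = stats::sd(w),
    without_mean = mean(o), without_sd = stats::sd(o),
    relative_difference_pct = relative_difference(mean(w), mean(o)),
    p_value_paired = wilcoxon_test(w, o, paired = TRUE)$p_value,
    p_value_ranksum = wilcoxon_test(w, o, paired = FALSE)$p_value
  )
}

#' Round half away from zero to a number of decimals
#'
#' Matches the rounding convention of printed clinical tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
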