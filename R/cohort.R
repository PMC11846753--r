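# Synthetic cohort generator at two fidelity levels: predictor tables
# drawn from configurable per-group truncated-normal distributions (for
# the statistics and prediction stages), and full contour patients with
# pressure/flow waveforms (for the geometry and mechanics stages).

#' Canonical predictor names
#'
#' The 13 predictors used for erosion prediction. `min_fss_dyn_cm2` is
#' reported in comparisons but is not a predictor.
#'
#' @return Character vector of 13 names.
#' @export
erosion_predictors <- function() {
  c("max_pws_kpa", "mean_pws_kpa", "max_pwsn", "mean_pwsn",
    "max_fss_dyn_cm2", "mean_fss_dyn_cm2", "max_dfss_dyn_cm2",
    "mean_dfss_dyn_cm2", "mean_plaque_burden", "area_stenosis",
    "min_cap_thickness_um", "mean_cap_thickness_um", "mean_lumen_area_mm2")
}

#' Default per-group predictor distributions
#'
#' Group means and SDs for the 13 predictors. The stress, strain,
#' shear-stress, morphology and cap-thickness rows carry the eroded and
#' non-eroded cohort statistics shipped with the package fixtures; the
#' dFSS and lumen-area rows are package defaults (no per-patient values
#' are published for them). Truncation bounds are physical floors.
#'
#' @return Tibble with columns `predictor`, `eroded_mean`, `eroded_sd`,
#'   `non_eroded_mean`, `non_eroded_sd`, `lower`, `upper`.
#' @export
default_group_params <- function() {
  tibble::tribble(
    ~predictor,              ~eroded_mean, ~eroded_sd, ~non_eroded_mean, ~non_eroded_sd, ~lower, ~upper,
    "max_pws_kpa",                  243.0,       95.1,            263.6,           71.9,      0,    Inf,
    "mean_pws_kpa",                  83.2,       25.8,            107.8,           22.7,      0,    Inf,
    "max_pwsn",                    0.1988,     0.0754,           0.1818,         0.0260,      0,      1,
    "mean_pwsn",                   0.1037,     0.0093,           0.1135,         0.0094,      0,      1,
    "max_fss_dyn_cm2",             127.96,      35.77,            72.69,          47.26,      0,    Inf,
    "mean_fss_dyn_cm2",             49.24,      21.86,            30.54,          18.74,      0,    Inf,
    "max_dfss_dyn_cm2",              90.0,       30.0,             40.0,           25.0,      0,    Inf,
    "mean_dfss_dyn_cm2",             35.0,       15.0,             17.0,           12.0,      0,    Inf,
    "mean_plaque_burden",           0.530,      0.111,            0.492,          0.046,      0,      1,
    "area_stenosis",                0.654,      0.187,            0.495,          0.213,      0,      1,
    "min_cap_thickness_um",         130.0,       82.0,            202.0,           83.0,      0,    Inf,
    "mean_cap_thickness_um",        309.0,      126.0,            394.0,          141.0,      0,    Inf,
    "mean_lumen_area_mm2",            4.5,        1.5,              5.5,            1.8,      0,    Inf
  )
}

#' Synthetic cohort configuration
#'
#' @param n_eroded,n_non_eroded Group sizes (>= 0).
#' @param seed Integer RNG seed.
#' @param group_params Per-predictor group distributions, as
#'   [default_group_params()].
#' @param effect_scale Multiplier on the between-group mean differences
#'   about the pooled mean; 0 gives a null cohort, 1 the configured
#'   effect sizes.
#' @param correlation Optional predictor correlation matrix (Gaussian
#'   copula); default identity (independent predictors).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_eroded = 8, n_non_eroded = 8, seed = 1,
                          group_params = default_group_params(),
                          effect_scale = 1, correlation = NULL) {
  stopifnot(n_eroded >= 0, n_non_eroded >= 0, effect_scale >= 0)
  req <- c("predictor", "eroded_mean", "eroded_sd", "non_eroded_mean",
           "non_eroded_sd", "lower", "upper")
  stopifnot(all(req %in% names(group_params)))
  num <- unlist(group_params[c("eroded_mean", "eroded_sd", "non_eroded_mean", "non_eroded_sd")])
  if (!all(is.finite(num))) stop("non-finite group parameter", call. = FALSE)
  if (any(group_params$eroded_sd < 0) || any(group_params$non_eroded_sd < 0)) {
    stop("group SDs must be nonnegative", call. = FALSE)
  }
  p <- nrow(group_params)
  if (!is.null(correlation)) {
    stopifnot(is.matrix(correlation), nrow(correlation) == p, ncol(correlation) == p)
  }
  structure(
    list(n_eroded = as.integer(n_eroded), n_non_eroded = as.integer(n_non_eroded),
         seed = as.integer(seed), group_params = group_params,
         effect_scale = effect_scale, correlation = correlation),
    class = "cohort_config"
  )
}

# truncated-normal quantile transform of uniforms
qtruncnorm <- function(u, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, length(u)))
  a <- stats::pnorm((lower - mean) / sd)
  b <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(a + u * (b - a))
}

#' Generate a synthetic predictor cohort
#'
#' Draws one row per synthetic patient with all 13 predictors from
#' per-group truncated-normal distributions (independent by default, or a
#' Gaussian copula when a correlation matrix is configured). Reproducible
#' from the configured seed.
#'
#' @param config A [cohort_config()].
#' @return Tibble with `patient_id`, `label` ("erosion"/"no_erosion") and
#'   the 13 predictor columns.
#' @export
generate_predictor_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gp <- config$group_params
  p <- nrow(gp)
  pooled <- (gp$eroded_mean + gp$non_eroded_mean) / 2
  mu_er <- pooled + config$effect_scale * (gp$eroded_mean - pooled)
  mu_ne <- pooled + config$effect_scale * (gp$non_eroded_mean - pooled)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  draw_group <- function(n, mu, sd) {
    if (n == 0) {
      m <- matrix(numeric(0), nrow = 0, ncol = p)
      colnames(m) <- gp$predictor
      return(m)
    }
    if (is.null(config$correlation)) {
      u <- matrix(stats::runif(n * p), nrow = n)
    } else {
      z <- matrix(stats::rnorm(n * p), nrow = n) %*% chol(config$correlation)
      u <- stats::pnorm(z)
    }
    m <- vapply(seq_len(p), function(j) {
      qtruncnorm(u[, j], mu[j], sd[j], gp$lower[j], gp$upper[j])
    }, numeric(n))
    m <- matrix(m, nrow = n)
    colnames(m) <- gp$predictor
    m
  }
  er <- draw_group(config$n_eroded, mu_er, gp$eroded_sd)
  ne <- draw_group(config$n_non_eroded, mu_ne, gp$non_eroded_sd)
  out <- tibble::as_tibble(rbind(er, ne))
  out$label <- rep(c("erosion", "no_erosion"), c(config$n_eroded, config$n_non_eroded))
  out$patient_id <- sprintf("S%03d", seq_len(nrow(out)))
  dplyr::relocate(out, "patient_id", "label")
}

#' Generate a synthetic contour patient
#'
#' Builds a slice stack of perturbed-ellipse lumens with a focal narrowing
#' that achieves the requested area stenosis exactly (all slices share one
#' angular shape, so areas scale with the squared radius factor), a wall
#' that thickens at the lesion, an optional lipid pool, a pressure/flow
#' waveform, and - for eroded patients - a thrombus overlying the lumen on
#' a contiguous angular sector of the narrowest slice, with those lumen
#' points erosion-labeled.
#'
#' @param label "erosion" or "no_erosion".
#' @param seed Integer seed.
#' @param n_slices Number of slices (>= 3).
#' @param stenosis_target Target area stenosis in `[0, 1)`.
#' @param base_radius Proximal lumen radius, mm.
#' @param systolic,diastolic Blood pressure, mmHg.
#' @param with_lipid Add a lipid pool under the lesion shoulder.
#' @param n_points Lumen points per slice after resampling (default 100).
#' @return An object of class `synthetic_patient`.
#' @export
generate_contour_patient <- function(label = c("erosion", "no_erosion"), seed = 1,
                                     n_slices = 10, stenosis_target = 0.5,
                                     base_radius = 1.6, systolic = 120,
                                     diastolic = 80, with_lipid = TRUE,
                                     n_points = 100) {
  label <- match.arg(label)
  stopifnot(n_slices >= 3, stenosis_target >= 0, stenosis_target < 1)
  min_factor <- sqrt(1 - stenosis_target)
  if (base_radius * min_factor < 0.3) {
    stop("stenosis target unreachable within radii bounds", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  # one fixed angular shape for every slice: a gently perturbed circle
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  e1 <- stats::runif(1, 0.02, 0.06)
  e2 <- stats::runif(1, 0.01, 0.04)
  ph1 <- stats::runif(1, 0, 2 * pi)
  ph2 <- stats::runif(1, 0, 2 * pi)
  g <- 1 + e1 * cos(2 * th + ph1) + e2 * cos(3 * th + ph2)

  # focal narrowing centered mid-stack; radius factor smooth in slice index
  k <- seq_len(n_slices)
  k_mid <- ceiling(n_slices / 2)
  bump <- exp(-((k - k_mid) / (n_slices / 5))^2)
  # 0 at the proximal end (the stenosis reference slice), 1 at the lesion
  bump <- pmax(0, (bump - bump[1]) / (bump[k_mid] - bump[1]))
  radius_factor <- 1 - (1 - min_factor) * bump

  lesion_slice <- which.min(radius_factor)
  slices <- vector("list", n_slices)
  for (i in k) {
    r_i <- base_radius * radius_factor[i]
    # per-slice rotation of the shape (area preserving)
    rot <- 2 * pi * (i - 1) / (n_slices * 7)
    gi <- 1 + e1 * cos(2 * (th - rot) + ph1) + e2 * cos(3 * (th - rot) + ph2)
    lumen <- tibble::tibble(x = r_i * gi * cos(th), y = r_i * gi * sin(th))
    # wall thickens at the lesion
    h <- 0.55 + 0.45 * bump[i] + 0.05 * cos(th + 0.5)
    outer <- tibble::tibble(x = (r_i * gi + h) * cos(th), y = (r_i * gi + h) * sin(th))
    lipid <- NULL
    if (with_lipid && bump[i] > 0.6) {
      # lipid leading edge behind a 100-degree sector of the lumen
      sector <- abs(((th - ph1) + pi) %% (2 * pi) - pi) < (50 * pi / 180)
      if (sum(sector) >= 5) {
        cap <- 0.13 + 0.1 * (1 - bump[i])
        lead_th <- th[sector]
        lead_r <- r_i * gi[sector] + cap
        lipid <- tibble::tibble(x = lead_r * cos(lead_th), y = lead_r * sin(lead_th))
      }
    }
    sl <- contour_slice(i - 1L, lumen, outer, lipid = lipid, validate = FALSE)
    if (!is.null(lipid)) sl <- complete_lipid_trailing_edge(sl)
    slices[[i]] <- resample_slice(sl, n_points = n_points)
  }

  if (label == "erosion") {
    # thrombus: a bump protruding into the lumen over a contiguous 60-degree
    # sector of the lesion slice
    sl <- slices[[lesion_slice]]
    lumen <- sl$lumen
    center <- attr(lumen, "fq_center")
    th_l <- atan2(lumen$y - center[2], lumen$x - center[1])
    r_l <- sqrt((lumen$x - center[1])^2 + (lumen$y - center[2])^2)
    th0 <- ph2 %% (2 * pi)
    ang_dist <- abs(((th_l - th0) + pi) %% (2 * pi) - pi)
    sector <- ang_dist < (30 * pi / 180)
    if (sum(sector) < 3) sector <- ang_dist < (45 * pi / 180)
    idx <- which(sector)
    # order sector points by angle to build the thrombus polygon
    idx <- idx[order(((th_l[idx] - th0 + pi) %% (2 * pi)))]
    depth <- 0.25 * min(r_l[idx])
    inner_r <- r_l[idx] - depth * cos(ang_dist[idx] / (30 * pi / 180) * (pi / 2))
    outer_r <- r_l[idx] + 0.02   # just beyond the lumen line
    thrombus <- tibble::tibble(
      x = center[1] + c(inner_r * cos(th_l[idx]), rev(outer_r * cos(th_l[idx]))),
      y = center[2] + c(inner_r * sin(th_l[idx]), rev(outer_r * sin(th_l[idx])))
    )
    mask <- rep(FALSE, nrow(lumen))
    mask[sector] <- TRUE
    sl$thrombus <- thrombus
    sl$erosion_mask <- mask
    slices[[lesion_slice]] <- sl
  }

  geometry <- vessel_geometry(slices, slice_spacing = 0.2)
  structure(
    list(patient_id = sprintf("SYN-%s-%d", substr(label, 1, 2), seed),
         label = label, geometry = geometry,
         waveform = make_waveform(systolic, diastolic),
         systolic = systolic, diastolic = diastolic,
         lesion_slice = lesion_slice - 1L),
    class = "synthetic_patient"
  )
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient %s> label %s, %d slices, BP %g/%g mmHg\n",
              x$patient_id, x$label, length(x$geometry$slices), x$systolic, x$diastolic))
  invisible(x)
}

#' Write a predictor cohort to CSV
#' @param cohort Tibble from [generate_predictor_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Serialize a contour patient to JSON
#'
#' Per-slice point lists in mm with 0-based slice indices and
#' counterclockwise point order.
#'
#' @param patient A `synthetic_patient`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_json <- function(patient, path) {
  stopifnot(inherits(patient, "synthetic_patient"))
  slices <- lapply(patient$geometry$slices, function(s) {
    out <- list(
      slice_index = s$slice_index,
      lumen = unname(as.matrix(s$lumen[c("x", "y")])),
      outer = unname(as.matrix(s$outer[c("x", "y")]))
    )
    if (!is.null(s$lipid)) out$lipid <- unname(as.matrix(s$lipid[c("x", "y")]))
    if (!is.null(s$thrombus)) out$thrombus <- unname(as.matrix(s$thrombus[c("x", "y")]))
    if (!is.null(s$erosion_mask)) out$erosion_mask <- s$erosion_mask
    out
  })
  jsonlite::write_json(
    list(patient_id = patient$patient_id, label = patient$label,
         systolic_mmhg = patient$systolic, diastolic_mmhg = patient$diastolic,
         slice_spacing_cm = patient$geometry$slice_spacing, slices = slices),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a contour patient from JSON
#' @param path Path written by [write_patient_json()].
#' @return A `synthetic_patient`.
#' @export
read_patient_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  slices <- lapply(seq_len(nrow2(j$slices)), function(i) {
    s <- slice_record(j$slices, i)
    contour_slice(
      s$slice_index,
      lumen = tibble::tibble(x = s$lumen[, 1], y = s$lumen[, 2]),
      outer = tibble::tibble(x = s$outer[, 1], y = s$outer[, 2]),
      lipid = if (!is.null(s$lipid)) tibble::tibble(x = s$lipid[, 1], y = s$lipid[, 2]),
      thrombus = if (!is.null(s$thrombus)) tibble::tibble(x = s$thrombus[, 1], y = s$thrombus[, 2]),
      erosion_mask = if (!is.null(s$erosion_mask)) as.logical(s$erosion_mask),
      validate = FALSE
    )
  })
  structure(
    list(patient_id = j$patient_id, label = j$label,
         geometry = vessel_geometry(slices, slice_spacing = j$slice_spacing_cm),
         waveform = make_waveform(j$systolic_mmhg, j$diastolic_mmhg),
         systolic = j$systolic_mmhg, diastolic = j$diastolic_mmhg),
    class = "synthetic_patient"
  )
}

nrow2 <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
slice_record <- function(slices, i) {
  if (is.data.frame(slices)) lapply(slices, function(col) {
    v <- col[[i]]
    if (is.list(v) && length(v) == 1) v[[1]] else v
  }) else slices[[i]]
}
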