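# Morphology metrics: lumen/wall areas, plaque burden, area stenosis,
# cap and wall thickness, and the preshrink to a zero-load state.

#' Lumen area of a slice
#' @param slice A [contour_slice()].
#' @return Area in mm^2.
#' @export
lumen_area <- function(slice) {
  stopifnot(inherits(slice, "contour_slice"))
  polygon_area(slice$lumen)
}

#' Wall area of a slice (area inside the outer boundary)
#' @param slice A [contour_slice()].
#' @return Area in mm^2.
#' @export
wall_area <- function(slice) {
  stopifnot(inherits(slice, "contour_slice"))
  polygon_area(slice$outer)
}

#' Plaque burden of a slice
#'
#' `1 - lumen area / wall area`, in [0, 1).
#'
#' @param slice A [contour_slice()].
#' @return Fraction.
#' @export
plaque_burden <- function(slice) {
  la <- lumen_area(slice)
  wa <- wall_area(slice)
  if (wa <= 0) stop("wall area must be positive", call. = FALSE)
  if (la > wa) stop("lumen area exceeds wall area", call. = FALSE)
  1 - la / wa
}

#' Area stenosis of a vessel segment
#'
#' `1 - min lumen area / reference lumen area`, where the reference is the
#' largest lumen area among slices proximal to (lower index than) the
#' minimum-lumen slice, falling back to the first slice.
#'
#' @param geometry A [vessel_geometry()].
#' @return Fraction in [0, 1).
#' @export
stenosis_by_area <- function(geometry) {
  stopifnot(inherits(geometry, "vessel_geometry"), length(geometry$slices) >= 2)
  areas <- vapply(geometry$slices, lumen_area, numeric(1))
  i_min <- which.min(areas)
  ref <- if (i_min > 1) max(areas[seq_len(i_min - 1)]) else areas[1]
  if (ref <= 0) stop("reference lumen area is zero", call. = FALSE)
  1 - areas[i_min] / ref
}

# thickness from each lumen point to the first crossing of `boundary`
# along the outward ray from the lumen centroid; NA where the ray misses
ray_thickness <- function(slice, boundary) {
  lumen <- slice$lumen
  center <- polygon_centroid(lumen)
  dx <- lumen$x - center[1]; dy <- lumen$y - center[2]
  r0 <- sqrt(dx^2 + dy^2)
  vapply(seq_len(nrow(lumen)), function(i) {
    dir <- c(dx[i], dy[i]) / r0[i]
    ts <- ray_polygon_intersections(center, dir, boundary)
    ts <- ts[ts > r0[i] - 1e-9]
    if (length(ts) == 0) NA_real_ else ts[[1]] - r0[i]
  }, numeric(1))
}

#' Per-point wall thickness
#'
#' Distance from each lumen point to the outer boundary along the outward
#' ray from the lumen centroid.
#'
#' @param slice A [contour_slice()].
#' @return Numeric vector (mm), one value per lumen point.
#' @export
wall_thickness <- function(slice) {
  stopifnot(inherits(slice, "contour_slice"))
  ray_thickness(slice, slice$outer)
}

#' Fibrous-cap thickness over the lipid core
#'
#' For each lumen point whose outward ray intersects the lipid leading
#' edge, the cap thickness is the distance from the lumen point to the
#' first lipid crossing. Points whose ray misses the lipid contribute
#' nothing; rays that fail inside the wall ring are excluded with a
#' warning.
#'
#' @param slice A [contour_slice()] with a lipid polygon.
#' @return A tibble with `point_index` (1-based lumen point) and
#'   `cap_thickness_mm`, plus attributes `min` and `mean` over cap points.
#' @export
cap_thickness <- function(slice) {
  stopifnot(inherits(slice, "contour_slice"))
  if (is.null(slice$lipid)) {
    out <- tibble::tibble(point_index = integer(0), cap_thickness_mm = numeric(0))
    attr(out, "min") <- NA_real_
    attr(out, "mean") <- NA_real_
    return(out)
  }
  wt <- wall_thickness(slice)
  ct <- ray_thickness(slice, slice$lipid)
  over_wall <- !is.na(ct) & !is.na(wt) & (ct > wt + 1e-9)
  if (any(over_wall)) {
    warning(sprintf("%d cap rays left the wall ring; points excluded", sum(over_wall)),
            call. = FALSE)
    ct[over_wall] <- NA_real_
  }
  keep <- which(!is.na(ct))
  out <- tibble::tibble(point_index = keep, cap_thickness_mm = ct[keep])
  attr(out, "min") <- if (length(keep)) min(out$cap_thickness_mm) else NA_real_
  attr(out, "mean") <- if (length(keep)) mean(out$cap_thickness_mm) else NA_real_
  out
}

#' Per-slice morphology table
#'
#' @param geometry A [vessel_geometry()].
#' @return Tibble with one row per slice: `slice_index`, `lumen_area_mm2`,
#'   `wall_area_mm2`, `plaque_burden`, `min_cap_thickness_mm`,
#'   `mean_cap_thickness_mm`.
#' @export
morphology_table <- function(geometry) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  purrr::map_dfr(geometry$slices, function(s) {
    ct <- cap_thickness(s)
    tibble::tibble(
      slice_index = s$slice_index,
      lumen_area_mm2 = lumen_area(s),
      wall_area_mm2 = wall_area(s),
      plaque_burden = plaque_burden(s),
      min_cap_thickness_mm = attr(ct, "min"),
      mean_cap_thickness_mm = attr(ct, "mean"),
      n_cap_points = nrow(ct)
    )
  })
}

#' Patient-level morphology summary
#'
#' Pools cap points across slices for the patient-level cap statistics and
#' averages plaque burden and lumen area over slices.
#'
#' @param geometry A [vessel_geometry()].
#' @return One-row tibble with `mean_plaque_burden`, `area_stenosis`,
#'   `min_cap_thickness_um`, `mean_cap_thickness_um`, `mean_lumen_area_mm2`.
#' @export
patient_morphology <- function(geometry) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  caps <- unlist(lapply(geometry$slices, function(s) cap_thickness(s)$cap_thickness_mm))
  tab <- morphology_table(geometry)
  tibble::tibble(
    mean_plaque_burden = mean(tab$plaque_burden),
    area_stenosis = stenosis_by_area(geometry),
    min_cap_thickness_um = if (length(caps)) 1000 * min(caps) else NA_real_,
    mean_cap_thickness_um = if (length(caps)) 1000 * mean(caps) else NA_real_,
    mean_lumen_area_mm2 = mean(tab$lumen_area_mm2)
  )
}

scale_polygon <- function(poly, factor, center = polygon_centroid(poly)) {
  tibble::tibble(
    x = center[1] + factor * (poly$x - center[1]),
    y = center[2] + factor * (poly$y - center[2])
  )
}

shrink_slice <- function(slice, s) {
  center <- polygon_centroid(slice$lumen)
  out <- slice
  out$lumen <- scale_polygon(slice$lumen, 1 - s, center)
  out$outer <- scale_polygon(slice$outer, 1 - s, center)
  if (!is.null(slice$lipid)) out$lipid <- scale_polygon(slice$lipid, 1 - s, center)
  if (!is.null(slice$calcification)) out$calcification <- scale_polygon(slice$calcification, 1 - s, center)
  out
}

#' Preshrink a vessel geometry to its zero-load state
#'
#' In vivo contours are imaged under pressure and axial stretch. The
#' zero-load state is obtained by shrinking each slice: axially by a fixed
#' fraction (default 5%), and circumferentially by a per-slice fraction
#' `s` found by root bracketing so that re-pressurizing the shrunken slice
#' recovers the in vivo lumen area within `tol` (relative, default 0.5%).
#'
#' @param geometry In vivo [vessel_geometry()].
#' @param pressure_kpa Lumen pressure used for the re-pressurization
#'   (typically the patient's mean or systolic pressure, kPa).
#' @param axial_shrink Axial shrink fraction (default 0.05); axial stretch
#'   applied on re-pressurization is `1 / (1 - axial_shrink)`.
#' @param target_lumen_areas Optional per-slice in vivo lumen areas (mm^2);
#'   default the geometry's own lumen areas.
#' @param mechanics_oracle Function `(shrunk_slice, pressure_kpa,
#'   axial_stretch) -> pressurized lumen area (mm^2)`. Defaults to the
#'   equivalent-tube inflation of [inflate_tube()] with `params`.
#' @param params Material parameters for the default oracle (default
#'   vessel wall of [default_materials()]).
#' @param tol Relative lumen-area mismatch tolerance (default 0.005).
#' @param s_max Largest circumferential shrink considered (default 0.3).
#' @return The zero-load geometry with `axial_shrink` and
#'   `circumferential_shrink` set, and a `preshrink_record` attribute
#'   (tibble: slice_index, shrink, residual).
#' @export
apply_preshrink <- function(geometry, pressure_kpa, axial_shrink = 0.05,
                            target_lumen_areas = NULL, mechanics_oracle = NULL,
                            params = NULL, tol = 0.005, s_max = 0.3) {
  stopifnot(inherits(geometry, "vessel_geometry"), pressure_kpa >= 0)
  lambda_z <- 1 / (1 - axial_shrink)
  if (is.null(target_lumen_areas)) {
    target_lumen_areas <- vapply(geometry$slices, lumen_area, numeric(1))
  }
  stopifnot(length(target_lumen_areas) == length(geometry$slices))
  if (is.null(mechanics_oracle)) {
    if (is.null(params)) params <- default_materials()$vessel
    mechanics_oracle <- function(shrunk_slice, p_kpa, lz) {
      r_in <- sqrt(lumen_area(shrunk_slice) / pi)
      r_out <- sqrt(wall_area(shrunk_slice) / pi)
      st <- inflate_tube(r_in, r_out, params, p_kpa, lz)
      pi * st$r_in^2
    }
  }

  n <- length(geometry$slices)
  shrinks <- numeric(n)
  residuals <- numeric(n)
  for (k in seq_len(n)) {
    target <- target_lumen_areas[k]
    f <- function(s) mechanics_oracle(shrink_slice(geometry$slices[[k]], s), pressure_kpa, lambda_z) - target
    f0 <- f(0)
    if (abs(f0) / target <= tol) {
      # already matching without circumferential shrink (e.g. zero pressure)
      shrinks[k] <- 0
      residuals[k] <- abs(f0) / target
      next
    }
    fmax <- f(s_max)
    if (sign(f0) == sign(fmax)) {
      best <- min(abs(f0), abs(fmax)) / target
      stop(sprintf(
        "preshrink bracket not found for slice %d in s = [0, %.2f]; best residual %.3g",
        geometry$slices[[k]]$slice_index, s_max, best), call. = FALSE)
    }
    root <- stats::uniroot(f, c(0, s_max), tol = 1e-6)
    shrinks[k] <- root$root
    residuals[k] <- abs(f(root$root)) / target
    if (residuals[k] > tol) {
      stop(sprintf("preshrink residual %.3g exceeds tolerance on slice %d",
                   residuals[k], geometry$slices[[k]]$slice_index), call. = FALSE)
    }
  }
  out_slices <- purrr::map2(geometry$slices, shrinks, shrink_slice)
  out <- vessel_geometry(out_slices, slice_spacing = geometry$slice_spacing,
                         centerline = geometry$centerline,
                         axial_shrink = axial_shrink,
                         circumferential_shrink = shrinks)
  attr(out, "preshrink_record") <- tibble::tibble(
    slice_index = vapply(geometry$slices, function(s) s$slice_index, integer(1)),
    shrink = shrinks, residual = residuals
  )
  out
}
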