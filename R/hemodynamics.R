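# Flow shear stress surrogate: Poiseuille base shear on the equivalent
# circular lumen, modulated by the local centroid-to-point radius so that
# narrow sectors carry elevated shear. FSS in dyn/cm^2 (1 dyn/cm^2 =
# 0.1 Pa).

#' Blood flow parameters
#'
#' @param mu Dynamic viscosity, dyn s/cm^2 (default 0.035 = 3.5 cP).
#' @param rho Density, g/cm^3 (default 1.05).
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(mu = 0.035, rho = 1.05) {
  stopifnot(mu > 0, rho > 0)
  structure(list(mu = mu, rho = rho), class = "flow_params")
}

#' Per-point flow shear stress on a slice lumen
#'
#' Base shear is the Poiseuille value on the equivalent circle,
#' `tau = 4 mu q / (pi r_eq^3)` with `r_eq = sqrt(lumen area / pi)`; each
#' lumen point is modulated by `(r_eq / rho_i)` where `rho_i` is its
#' centroid-to-point radius, so locally narrower sectors see higher shear.
#'
#' @param slice A [contour_slice()] with a resampled lumen.
#' @param q_mls Volumetric flow, mL/s (>= 0).
#' @param flow A [flow_params()].
#' @param alpha Exponent of the local-radius modulation (default 1).
#' @return Tibble with `point_index`, `fss_dyn_cm2`.
#' @export
slice_fss <- function(slice, q_mls, flow = flow_params(), alpha = 1) {
  stopifnot(inherits(slice, "contour_slice"), q_mls >= 0)
  area_cm2 <- lumen_area(slice) / 100   # mm^2 -> cm^2
  if (area_cm2 <= 0) stop("zero lumen area", call. = FALSE)
  r_eq <- sqrt(area_cm2 / pi)           # cm
  tau_bar <- 4 * flow$mu * q_mls / (pi * r_eq^3)
  lumen <- slice$lumen
  center <- polygon_centroid(lumen)
  rho_cm <- sqrt((lumen$x - center[1])^2 + (lumen$y - center[2])^2) / 10  # mm -> cm
  tau <- tau_bar * (r_eq / rho_cm)^alpha
  tibble::tibble(point_index = seq_len(nrow(lumen)), fss_dyn_cm2 = pmax(tau, 0))
}

#' Pointwise FSS difference between the pressure extremes
#'
#' `dFSS = FSS(maxP) - FSS(minP)` per slice point; may be negative when
#' the flow at minimum pressure exceeds the flow at maximum pressure.
#'
#' @param field A `biomech_field` tibble from [evaluate_timepoints()].
#' @return Tibble with `slice_index`, `point_index`, `dfss_dyn_cm2`.
#' @export
delta_fss <- function(field) {
  stopifnot(is.data.frame(field),
            all(c("slice_index", "point_index", "time_point", "fss_dyn_cm2") %in% names(field)))
  wide <- tidyr::pivot_wider(
    dplyr::select(field, "slice_index", "point_index", "time_point", "fss_dyn_cm2"),
    names_from = "time_point", values_from = "fss_dyn_cm2"
  )
  if (!all(c("maxP", "minP") %in% names(wide)) || anyNA(wide$maxP) || anyNA(wide$minP)) {
    stop("field must hold both time points for every slice point", call. = FALSE)
  }
  tibble::tibble(
    slice_index = wide$slice_index,
    point_index = wide$point_index,
    dfss_dyn_cm2 = wide$maxP - wide$minP
  )
}
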