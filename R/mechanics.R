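# Quasi-static structural surrogate: inflation-extension of an
# incompressible hyperelastic thick-walled tube, solved per lumen point
# with that point's local radius and wall thickness. Yields plaque wall
# stress (max principal Cauchy stress, kPa) and strain (max principal
# Green-Lagrange strain) at the lumen surface.

# circumferential/axial/radial deviatoric stress differences at local
# stretches; fiber along theta
tube_dev <- function(lam_r, lam_t, lam_z, params) {
  I1 <- lam_r^2 + lam_t^2 + lam_z^2
  e1 <- params$D2 * (I1 - 3)
  W1 <- params$c1 + params$D1 * params$D2 * exp(pmin(e1, 700))
  W2 <- params$c2
  I4 <- lam_t^2
  W4 <- if (params$K1 != 0) {
    2 * params$K1 * (I4 - 1) * exp(pmin(params$K2 * (I4 - 1)^2, 700))
  } else 0
  list(
    tt_rr = 2 * W1 * (lam_t^2 - lam_r^2) - 2 * W2 * (lam_t^-2 - lam_r^-2) + 2 * W4 * lam_t^2,
    zz_rr = 2 * W1 * (lam_z^2 - lam_r^2) - 2 * W2 * (lam_z^-2 - lam_r^-2)
  )
}

# stretches across the deformed wall for deformed inner radius r_in
tube_stretches <- function(r, r_in, R_in, lambda_z) {
  R <- sqrt(pmax(R_in^2 + lambda_z * (r^2 - r_in^2), 1e-300))
  lam_t <- r / R
  lam_r <- 1 / (lam_t * lambda_z)
  list(R = R, lam_t = lam_t, lam_r = lam_r)
}

# lumen pressure carried by the wall for a given deformed inner radius
tube_pressure <- function(r_in, R_in, R_out, params, lambda_z, quad) {
  r_out <- sqrt(r_in^2 + (R_out^2 - R_in^2) / lambda_z)
  # map Gauss-Legendre nodes on [-1, 1] to [r_in, r_out]
  half <- (r_out - r_in) / 2
  mid <- (r_out + r_in) / 2
  r <- mid + half * quad$x
  st <- tube_stretches(r, r_in, R_in, lambda_z)
  dev <- tube_dev(st$lam_r, st$lam_t, lambda_z, params)
  sum(quad$w * dev$tt_rr / r) * half
}

gauss_legendre <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    # Golub-Welsch: eigen decomposition of the Jacobi matrix
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    ord <- order(x)
    res <- list(x = x[ord], w = w[ord])
    cache[[key]] <- res
    res
  }
})

#' Inflate an incompressible hyperelastic thick-walled tube
#'
#' Solves the quasi-static inflation-extension problem: given zero-load
#' radii, an axial stretch and a lumen pressure, the deformed inner radius
#' is found by root bracketing on the equilibrium pressure integral
#' `p = int_{r_in}^{r_out} (sigma_tt - sigma_rr) / r dr`, with the
#' boundary conditions `sigma_rr(r_in) = -p` and `sigma_rr(r_out) = 0`.
#' The fiber direction is circumferential.
#'
#' @param R_in,R_out Zero-load inner and outer radii (mm), `0 < R_in <
#'   R_out`.
#' @param params A [material_params()].
#' @param p_kpa Lumen pressure (kPa), >= 0.
#' @param lambda_z Axial stretch (> 0), default 1.
#' @param n_grid Number of radial grid points for the returned transmural
#'   profile (default 201).
#' @return An object of class `tube_state`: deformed radii, stretches, and
#'   a transmural tibble `grid` with `r, R, lam_t, sigma_rr_kpa,
#'   sigma_tt_kpa, sigma_zz_kpa, E_tt`; plus the verified pressure
#'   residual.
#' @export
inflate_tube <- function(R_in, R_out, params, p_kpa, lambda_z = 1, n_grid = 201) {
  stopifnot(R_in > 0, R_out > R_in, p_kpa >= 0, lambda_z > 0)
  quad <- gauss_legendre(48)
  g <- function(r_in) tube_pressure(r_in, R_in, R_out, params, lambda_z, quad) - p_kpa

  lo <- 0.3 * R_in / sqrt(lambda_z)
  hi <- 1.5 * R_in
  glo <- g(lo)
  ghi <- g(hi)
  tries <- 0
  while (sign(glo) == sign(ghi) && tries < 12) {
    hi <- hi * 1.5
    ghi <- tryCatch(g(hi), error = function(e) NA_real_)
    if (is.na(ghi)) break
    tries <- tries + 1
  }
  if (is.na(ghi) || sign(glo) == sign(ghi)) {
    stop(sprintf(
      "tube inflation found no equilibrium in r_in = [%.3g, %.3g] mm at p = %.3g kPa (material too soft or overflow)",
      lo, hi, p_kpa), call. = FALSE)
  }
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-12)
  r_in <- root$root
  r_out <- sqrt(r_in^2 + (R_out^2 - R_in^2) / lambda_z)

  # verify the equilibrium residual with adaptive quadrature
  integrand <- function(r) {
    st <- tube_stretches(r, r_in, R_in, lambda_z)
    dev <- tube_dev(st$lam_r, st$lam_t, lambda_z, params)
    dev$tt_rr / r
  }
  p_check <- stats::integrate(integrand, r_in, r_out, rel.tol = 1e-10,
                              abs.tol = 1e-12)$value
  residual <- abs(p_check - p_kpa)
  if (residual > 1e-6 * max(p_kpa, 1)) {
    stop(sprintf("tube solve residual %.3g kPa exceeds tolerance", residual), call. = FALSE)
  }

  # transmural profile; the cumulative radial-equilibrium integral is
  # evaluated on a 10x finer grid and subsampled, so sigma_rr honors both
  # boundary conditions to well under the solve tolerance
  refine <- 10L
  n_fine <- (n_grid - 1L) * refine + 1L
  r_fine <- seq(r_in, r_out, length.out = n_fine)
  st_f <- tube_stretches(r_fine, r_in, R_in, lambda_z)
  dev_f <- tube_dev(st_f$lam_r, st_f$lam_t, lambda_z, params)
  f_fine <- dev_f$tt_rr / r_fine
  h_f <- diff(r_fine)
  cum_fine <- c(0, cumsum((f_fine[-1] + f_fine[-n_fine]) / 2 * h_f))
  keep <- seq(1, n_fine, by = refine)
  r <- r_fine[keep]
  st <- tube_stretches(r, r_in, R_in, lambda_z)
  dev <- tube_dev(st$lam_r, st$lam_t, lambda_z, params)
  sigma_rr <- -p_kpa + cum_fine[keep]
  grid <- tibble::tibble(
    r = r, R = st$R, lam_t = st$lam_t,
    sigma_rr_kpa = sigma_rr,
    sigma_tt_kpa = sigma_rr + dev$tt_rr,
    sigma_zz_kpa = sigma_rr + dev$zz_rr,
    E_tt = (st$lam_t^2 - 1) / 2
  )
  structure(
    list(R_in = R_in, R_out = R_out, r_in = r_in, r_out = r_out,
         lambda_z = lambda_z, p_kpa = p_kpa, grid = grid,
         residual_kpa = residual, params = params),
    class = "tube_state"
  )
}

#' @export
print.tube_state <- function(x, ...) {
  cat(sprintf("<tube_state> R [%.3f, %.3f] -> r [%.3f, %.3f] mm at p = %.2f kPa, lambda_z = %.3f\n",
              x$R_in, x$R_out, x$r_in, x$r_out, x$p_kpa, x$lambda_z))
  invisible(x)
}

#' Recompute the equilibrium pressure from a tube state's profile
#'
#' Integrates `(sigma_tt - sigma_rr) / r` over the stored transmural grid
#' (monotone spline + adaptive quadrature) and returns the absolute
#' difference from the imposed lumen pressure.
#'
#' @param state A `tube_state`.
#' @return Absolute residual in kPa.
#' @export
tube_equilibrium_residual <- function(state) {
  g <- state$grid
  f <- stats::splinefun(g$r, (g$sigma_tt_kpa - g$sigma_rr_kpa) / g$r, method = "natural")
  p <- stats::integrate(f, min(g$r), max(g$r), rel.tol = 1e-10)$value
  abs(p - state$p_kpa)
}

# lumen-surface principal values from a tube state
tube_surface_values <- function(state) {
  g1 <- state$grid[1, ]
  lam_t <- g1$lam_t
  lam_r <- 1 / (lam_t * state$lambda_z)
  pws <- max(g1$sigma_rr_kpa, g1$sigma_tt_kpa, g1$sigma_zz_kpa)
  strains <- (c(lam_r, lam_t, state$lambda_z)^2 - 1) / 2
  list(pws_kpa = pws, pwsn = max(strains))
}

# thickness-weighted blend of vessel and lipid parameters for lumen
# points backed by a lipid core (series two-layer composite collapsed to
# one equivalent material)
blend_materials <- function(vessel, lipid, w_lipid) {
  w <- min(max(w_lipid, 0), 1)
  material_params(
    tissue_type = "composite",
    c1 = (1 - w) * vessel$c1 + w * lipid$c1,
    c2 = (1 - w) * vessel$c2 + w * lipid$c2,
    D1 = (1 - w) * vessel$D1 + w * lipid$D1,
    D2 = (1 - w) * vessel$D2 + w * lipid$D2,
    K1 = (1 - w) * vessel$K1,
    K2 = vessel$K2,
    fiber_direction = vessel$fiber_direction
  )
}

#' Per-point plaque wall stress and strain for one slice
#'
#' Each resampled lumen point is assigned the lumen-surface maximum
#' principal Cauchy stress (PWS) and Green-Lagrange strain (PWSn) of an
#' equivalent-tube inflation using that point's local zero-load radius and
#' wall thickness. Points backed by a lipid core use a two-layer composite
#' (cap = vessel, core = lipid) with thickness-weighted stiffness.
#'
#' @param zero_load_slice The zero-load [contour_slice()] (resampled lumen).
#' @param params Material set: a list with `vessel` and `lipid` entries
#'   (default [default_materials()]).
#' @param p_kpa Lumen pressure (kPa).
#' @param lambda_z Axial stretch.
#' @return Tibble with `point_index`, `pws_kpa`, `pwsn`.
#' @export
slice_pws <- function(zero_load_slice, params = default_materials(), p_kpa,
                      lambda_z = 1) {
  stopifnot(inherits(zero_load_slice, "contour_slice"))
  lumen <- zero_load_slice$lumen
  center <- polygon_centroid(lumen)
  radius <- sqrt((lumen$x - center[1])^2 + (lumen$y - center[2])^2)
  thick <- wall_thickness(zero_load_slice)
  if (any(is.na(thick)) || any(thick <= 0)) {
    stop("non-positive or undefined local wall thickness", call. = FALSE)
  }
  lipid_frac <- rep(0, nrow(lumen))
  if (!is.null(zero_load_slice$lipid)) {
    cap <- ray_thickness(zero_load_slice, zero_load_slice$lipid)
    hit <- !is.na(cap) & cap < thick
    # lipid occupies from the leading edge to its trailing edge; measure
    # the lipid chord along the same ray
    if (any(hit)) {
      chord <- lipid_chord(zero_load_slice, which(hit))
      lipid_frac[hit] <- pmin(chord / thick[hit], 1)
    }
  }

  if (p_kpa == 0 && abs(lambda_z - 1) < 1e-12) {
    return(tibble::tibble(point_index = seq_len(nrow(lumen)), pws_kpa = 0, pwsn = 0))
  }

  # identical (radius, thickness, composite) points share one tube solve
  key <- paste(signif(radius, 12), signif(thick, 12), signif(lipid_frac, 12))
  uniq <- !duplicated(key)
  sol <- vector("list", nrow(lumen))
  lookup <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    pset <- if (lipid_frac[i] > 0) {
      blend_materials(params$vessel, params$lipid, lipid_frac[i])
    } else params$vessel
    st <- inflate_tube(radius[i], radius[i] + thick[i], pset, p_kpa, lambda_z)
    lookup[[key[i]]] <- tube_surface_values(st)
  }
  vals <- lapply(key, function(k) lookup[[k]])
  tibble::tibble(
    point_index = seq_len(nrow(lumen)),
    pws_kpa = vapply(vals, `[[`, numeric(1), "pws_kpa"),
    pwsn = vapply(vals, `[[`, numeric(1), "pwsn")
  )
}

# length of the intersection of the outward ray (per lumen point) with
# the lipid polygon
lipid_chord <- function(slice, idx) {
  lumen <- slice$lumen
  center <- polygon_centroid(lumen)
  vapply(idx, function(i) {
    dir <- c(lumen$x[i] - center[1], lumen$y[i] - center[2])
    dir <- dir / sqrt(sum(dir^2))
    ts <- ray_polygon_intersections(center, dir, slice$lipid)
    if (length(ts) < 2) return(0)
    max(ts) - min(ts)
  }, numeric(1))
}

#' Evaluate the biomechanical field at the pressure extremes
#'
#' Runs the structural surrogate (per-point equivalent tube) and the flow
#' shear surrogate at the times of maximum and minimum inlet pressure, for
#' every slice of a patient. Quasi-static: each time point is an
#' independent equilibrium solve.
#'
#' @param geometry In vivo [vessel_geometry()] (lumen contours resampled to
#'   100 points per slice).
#' @param zero_load Zero-load geometry from [apply_preshrink()]; if `NULL`
#'   the in vivo geometry is used unshrunk.
#' @param waveform A [make_waveform()] object.
#' @param params Material set (default [default_materials()]).
#' @param flow A [flow_params()] object.
#' @return A `biomech_field` tibble: `slice_index`, `point_index`,
#'   `time_point` ("maxP"/"minP"), `pws_kpa`, `pwsn`, `fss_dyn_cm2`,
#'   `erosion` (logical mask).
#' @export
evaluate_timepoints <- function(geometry, zero_load = NULL, waveform,
                                params = default_materials(),
                                flow = flow_params()) {
  stopifnot(inherits(geometry, "vessel_geometry"), inherits(waveform, "waveform"))
  if (is.null(zero_load)) zero_load <- geometry
  lambda_z <- 1 / (1 - zero_load$axial_shrink)
  times <- c(maxP = waveform$t_max_p, minP = waveform$t_min_p)
  out <- purrr::map_dfr(names(times), function(tp) {
    t <- times[[tp]]
    p_kpa <- mmhg_to_kpa(waveform$p_in(t))
    q <- waveform$q(t)
    purrr::map2_dfr(geometry$slices, zero_load$slices, function(sl, zl, ...) {
      solid <- tryCatch(
        slice_pws(zl, params = params, p_kpa = p_kpa, lambda_z = lambda_z),
        error = function(e) stop(sprintf("slice %d: %s", sl$slice_index, conditionMessage(e)),
                                 call. = FALSE)
      )
      fss <- slice_fss(sl, q_mls = q, flow = flow)
      mask <- sl$erosion_mask
      if (is.null(mask)) mask <- rep(FALSE, nrow(sl$lumen))
      tibble::tibble(
        slice_index = sl$slice_index,
        point_index = solid$point_index,
        time_point = tp,
        pws_kpa = solid$pws_kpa,
        pwsn = solid$pwsn,
        fss_dyn_cm2 = fss$fss_dyn_cm2,
        erosion = mask
      )
    })
  })
  class(out) <- c("biomech_field", class(out))
  out
}

#' Convert mmHg to kPa
#' @param p Pressure in mmHg.
#' @return Pressure in kPa (1 mmHg = 0.1333 kPa).
#' @export
mmhg_to_kpa <- function(p) 0.1333 * p
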