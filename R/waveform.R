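# Pressure and flow waveforms: a literature-shaped pulse prorated to the
# patient's arm-cuff systolic/diastolic pressures, with a diastolic-
# dominant coronary flow profile.

#' Build patient pressure and flow waveforms
#'
#' A smooth periodic pulse shape is rescaled so that the inlet pressure
#' spans exactly `[diastolic, systolic]` mmHg. The outlet pressure is a
#' scaled copy; the flow profile is nonnegative, periodic and
#' diastolic-dominant. The times of maximum and minimum inlet pressure are
#' located by dense sampling refined with a local optimizer.
#'
#' @param systolic,diastolic Arm-cuff pressures, mmHg (`systolic >
#'   diastolic > 0`).
#' @param period Cardiac period in s (default 0.8).
#' @param q_mean Mean flow in mL/s (default 1.0).
#' @param outlet_scale Outlet/inlet pressure ratio (default 0.98).
#' @return An object of class `waveform` with function fields `p_in(t)`,
#'   `p_out(t)`, `q(t)` and scalars `period`, `t_max_p`, `t_min_p`.
#' @export
make_waveform <- function(systolic, diastolic, period = 0.8, q_mean = 1.0,
                          outlet_scale = 0.98) {
  if (!(systolic > diastolic && diastolic > 0)) {
    stop("need systolic > diastolic > 0", call. = FALSE)
  }
  stopifnot(period > 0, q_mean >= 0)

  # pulse shape: sharp systolic upstroke, dicrotic notch, diastolic decay
  shape <- function(t) {
    ph <- (t / period) %% 1
    exp(1.2 * sin(2 * pi * ph)) + 0.25 * sin(4 * pi * ph + 0.8)
  }
  # locate the continuous extrema of the shape once, on a dense grid with
  # local refinement, then rescale to [diastolic, systolic]
  ph_grid <- seq(0, period, length.out = 4097)[-4097]
  sv <- shape(ph_grid)
  refine <- function(t0, maximize) {
    w <- period / 64
    o <- stats::optimize(shape, c(t0 - w, t0 + w), maximum = maximize, tol = 1e-12)
    if (maximize) c(o$maximum, o$objective) else c(o$minimum, o$objective)
  }
  mx <- refine(ph_grid[which.max(sv)], TRUE)
  mn <- refine(ph_grid[which.min(sv)], FALSE)
  s_max <- mx[2]; s_min <- mn[2]
  p_in <- function(t) {
    diastolic + (systolic - diastolic) * (shape(t) - s_min) / (s_max - s_min)
  }
  p_out <- function(t) outlet_scale * p_in(t)

  # diastolic-dominant coronary flow, nonnegative, phase-shifted so the
  # flow peak trails the pressure peak
  q_shape <- function(t) {
    ph <- (t / period) %% 1
    0.35 + 0.65 * exp(0.9 * sin(2 * pi * ph - 0.7))
  }
  q_norm <- mean(q_shape(ph_grid))
  q <- function(t) pmax(q_mean * q_shape(t) / q_norm, 0)

  t_max_p <- mx[1] %% period
  t_min_p <- mn[1] %% period
  structure(
    list(period = period, p_in = p_in, p_out = p_out, q = q,
         t_max_p = t_max_p, t_min_p = t_min_p,
         systolic = systolic, diastolic = diastolic),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %g/%g mmHg, period %.2f s, t_maxP = %.3f s, t_minP = %.3f s\n",
              x$systolic, x$diastolic, x$period, x$t_max_p, x$t_min_p))
  invisible(x)
}
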