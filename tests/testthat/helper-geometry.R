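# fixtures built in code: canonical contours and independent oracles

circle_polygon <- function(r = 1, n = 200, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  polygon_xy(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_polygon <- function(a = 2, b = 1, n = 200) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  polygon_xy(a * cos(th), b * sin(th))
}

star_polygon <- function(n = 120, seed = 1, r0 = 2, amp = 0.4) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- r0 + amp * sin(3 * th + runif(1, 0, 2 * pi)) + amp / 2 * cos(5 * th)
  polygon_xy(r * cos(th), r * sin(th))
}

# independent area oracle: fan triangulation from the first vertex
fan_triangulation_area <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  a <- 0
  for (i in 2:(n - 1)) {
    a <- a + ((x[i] - x[1]) * (y[i + 1] - y[1]) - (x[i + 1] - x[1]) * (y[i] - y[1])) / 2
  }
  abs(a)
}

# concentric circular slice: lumen radius r_in, outer radius r_out
circular_slice <- function(r_in = 1.5, r_out = 2.5, n = 200, index = 0,
                           lipid_lead_r = NULL, thrombus = NULL, erosion_mask = NULL) {
  lipid <- NULL
  if (!is.null(lipid_lead_r)) {
    th <- seq(0, 2 * pi, length.out = 121)[-121]
    lipid <- tibble::tibble(x = lipid_lead_r * cos(th), y = lipid_lead_r * sin(th))
  }
  contour_slice(index, circle_polygon(r_in, n), circle_polygon(r_out, n),
                lipid = lipid, thrombus = thrombus, erosion_mask = erosion_mask,
                validate = FALSE)
}

# uniform tube geometry of identical circular slices
uniform_geometry <- function(n_slices = 3, r_in = 1.5, r_out = 2.5, n = 200) {
  slices <- lapply(seq_len(n_slices) - 1, function(i) circular_slice(r_in, r_out, n, i))
  vessel_geometry(slices)
}

# volume-preserving random deformation gradient
random_volume_preserving_F <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9, sd = 0.15), 3, 3) + diag(3)
  M / det(M)^(1 / 3)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# ellipse quarter-perimeter via quadrature (independent of the resampler)
pracma_ellipke_perimeter <- function(a, b) {
  f <- function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2) / a
  stats::integrate(f, 0, pi / 2, rel.tol = 1e-10)$value
}
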