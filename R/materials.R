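# Modified Mooney-Rivlin strain-energy functions for vessel wall, lipid
# and calcification, with Cauchy stresses under incompressible
# homogeneous deformations.
#
# The anisotropic form adds an exponential fiber term acting along the
# circumferential unit vector n_c:
#   W = c1 (I1 - 3) + c2 (I2 - 3) + D1 [exp(D2 (I1 - 3)) - 1]
#       + (K1/K2) {exp[K2 (I4 - 1)^2] - 1}
# with I4 = n_c' C n_c. Isotropic tissues (lipid, calcification) have
# K1 = 0. Stresses are in kPa.

#' Material parameter set
#'
#' @param tissue_type One of "vessel", "lipid", "calcification".
#' @param c1,c2,D1 Mooney-Rivlin coefficients (kPa).
#' @param D2 Dimensionless isotropic exponent.
#' @param K1 Fiber stiffness (kPa); 0 for isotropic tissues.
#' @param K2 Dimensionless fiber exponent; must be > 0 when K1 != 0.
#' @param fiber_direction Unit vector of the circumferential (fiber)
#'   direction; default `c(1, 0, 0)`.
#' @return An object of class `material_params`.
#' @export
material_params <- function(tissue_type, c1, c2, D1, D2, K1 = 0, K2 = 1,
                            fiber_direction = c(1, 0, 0)) {
  stopifnot(is.numeric(c(c1, c2, D1, D2, K1, K2)), all(is.finite(c(c1, c2, D1, D2, K1, K2))))
  if (D2 <= 0) stop("D2 must be positive", call. = FALSE)
  if (K1 != 0 && K2 <= 0) stop("K2 must be positive when K1 is nonzero", call. = FALSE)
  nc <- fiber_direction / sqrt(sum(fiber_direction^2))
  structure(
    list(tissue_type = tissue_type, c1 = c1, c2 = c2, D1 = D1, D2 = D2,
         K1 = K1, K2 = K2, fiber_direction = nc),
    class = "material_params"
  )
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params %s> c1=%.4g c2=%.4g D1=%.4g D2=%.4g K1=%.4g K2=%.4g kPa\n",
              x$tissue_type, x$c1, x$c2, x$D1, x$D2, x$K1, x$K2))
  invisible(x)
}

#' Default material parameter sets
#'
#' Literature values for coronary vessel wall (anisotropic), lipid core and
#' calcification (isotropic). The vessel c1 is negative; the exponential
#' isotropic term dominates so the stress-stretch response is monotone
#' stiffening.
#'
#' @return Named list of [material_params()]: `vessel`, `lipid`,
#'   `calcification`.
#' @export
default_materials <- function() {
  list(
    vessel = material_params("vessel", c1 = -515.6, c2 = 45.05, D1 = 247.3,
                             D2 = 2.0, K1 = 14.1, K2 = 23.5),
    lipid = material_params("lipid", c1 = 0.5, c2 = 0, D1 = 0.5, D2 = 1.5),
    calcification = material_params("calcification", c1 = 920, c2 = 0,
                                    D1 = 360, D2 = 2.0)
  )
}

#' Read material parameter sets from a YAML config
#'
#' The file maps tissue-type names to parameter lists with keys
#' `c1, c2, D1, D2` and optionally `K1, K2`.
#'
#' @param path Path to a YAML file; default the config shipped with the
#'   package.
#' @return Named list of [material_params()].
#' @export
read_material_config <- function(path = system.file("extdata", "materials.yaml",
                                                    package = "plaquemech")) {
  cfg <- yaml::read_yaml(path)
  purrr::imap(cfg, function(p, nm) {
    material_params(nm, c1 = p$c1, c2 = p$c2, D1 = p$D1, D2 = p$D2,
                    K1 = p$K1 %||% 0, K2 = p$K2 %||% 1)
  })
}

#' Deformation invariants I1, I2, I4
#'
#' `I1 = tr C`, `I2 = (I1^2 - tr(C^2)) / 2`, `I4 = n_c' C n_c` with
#' `C = F' F`. F must be volume preserving.
#'
#' @param F 3x3 deformation gradient with `det F = 1` (tolerance 1e-8).
#' @param n_c Fiber direction (normalized with a warning if not unit).
#' @return Named numeric vector `c(I1, I2, I4)`.
#' @export
mr_invariants <- function(F, n_c = c(1, 0, 0)) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  d <- det(F)
  if (abs(d - 1) > 1e-8) {
    stop(sprintf("deformation gradient is not volume preserving (det F = %.10f)", d),
         call. = FALSE)
  }
  nn <- sqrt(sum(n_c^2))
  if (abs(nn - 1) > 1e-9) {
    warning("fiber direction was not a unit vector; normalized", call. = FALSE)
    n_c <- n_c / nn
  }
  C <- t(F) %*% F
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  I4 <- drop(t(n_c) %*% C %*% n_c)
  c(I1 = I1, I2 = I2, I4 = I4)
}

# partial derivatives of W wrt I1, I2, I4
mr_dW <- function(inv, params) {
  I1 <- inv[["I1"]]; I4 <- inv[["I4"]]
  e1 <- params$D2 * (I1 - 3)
  if (e1 > 700) stop(sprintf("exponential overflow at I1 = %.3f", I1), call. = FALSE)
  W1 <- params$c1 + params$D1 * params$D2 * exp(e1)
  W2 <- params$c2
  W4 <- 0
  if (params$K1 != 0) {
    e4 <- params$K2 * (I4 - 1)^2
    if (e4 > 700) stop(sprintf("exponential overflow at I4 = %.3f", I4), call. = FALSE)
    W4 <- 2 * params$K1 * (I4 - 1) * exp(e4)
  }
  list(W1 = W1, W2 = W2, W4 = W4)
}

#' Strain-energy density
#'
#' @param F 3x3 volume-preserving deformation gradient.
#' @param params A [material_params()].
#' @return Energy density in kPa; zero at the identity.
#' @export
strain_energy <- function(F, params) {
  inv <- mr_invariants(F, params$fiber_direction)
  I1 <- inv[["I1"]]; I2 <- inv[["I2"]]; I4 <- inv[["I4"]]
  e1 <- params$D2 * (I1 - 3)
  if (e1 > 700) stop(sprintf("exponential overflow at I1 = %.3f", I1), call. = FALSE)
  W <- params$c1 * (I1 - 3) + params$c2 * (I2 - 3) + params$D1 * (exp(e1) - 1)
  if (params$K1 != 0) {
    e4 <- params$K2 * (I4 - 1)^2
    if (e4 > 700) stop(sprintf("exponential overflow at I4 = %.3f", I4), call. = FALSE)
    W <- W + (params$K1 / params$K2) * (exp(e4) - 1)
  }
  W
}

#' Cauchy stress under an incompressible homogeneous deformation
#'
#' `sigma = -p I + 2 W1 B - 2 W2 B^{-1} + 2 W4 (F n_c)(F n_c)'` with the
#' pressure multiplier fixed by a traction-free direction:
#' `n_t' sigma n_t = 0`.
#'
#' @param F 3x3 volume-preserving deformation gradient.
#' @param params A [material_params()].
#' @param traction_free_dir Unit vector of the traction-free direction
#'   (required to fix the incompressibility pressure).
#' @return Symmetric 3x3 Cauchy stress (kPa); zero at the identity.
#' @export
cauchy_stress <- function(F, params, traction_free_dir = NULL) {
  if (is.null(traction_free_dir)) {
    stop("a traction-free direction is required to fix the pressure", call. = FALSE)
  }
  inv <- mr_invariants(F, params$fiber_direction)
  dW <- mr_dW(inv, params)
  B <- F %*% t(F)
  Binv <- solve(B)
  m <- F %*% params$fiber_direction
  dev <- 2 * dW$W1 * B - 2 * dW$W2 * Binv + 2 * dW$W4 * (m %*% t(m))
  nt <- traction_free_dir / sqrt(sum(traction_free_dir^2))
  p_tilde <- drop(t(nt) %*% dev %*% nt)
  sig <- dev - p_tilde * diag(3)
  (sig + t(sig)) / 2
}

#' Uniaxial stress-stretch curve
#'
#' Incompressible uniaxial extension along the circumferential (fiber) or
#' axial direction with equal lateral stretches `lambda^{-1/2}` and
#' traction-free lateral faces.
#'
#' @param params A [material_params()].
#' @param direction `"circumferential"` (along the fiber) or `"axial"`.
#' @param lambda_grid Stretch values in (0.5, 1.8).
#' @return Tibble with `lambda`, `stress_kpa`, `direction`, `tissue_type`.
#' @export
stress_stretch_curve <- function(params, direction = c("circumferential", "axial"),
                                 lambda_grid = seq(0.9, 1.3, by = 0.01)) {
  direction <- match.arg(direction)
  if (any(lambda_grid <= 0)) stop("stretches must be positive", call. = FALSE)
  # fiber along e1; circumferential pull stretches e1, axial pull e3
  axis <- if (direction == "circumferential") 1 else 3
  stress <- vapply(lambda_grid, function(lam) {
    stretches <- rep(lam^(-1 / 2), 3)
    stretches[axis] <- lam
    F <- diag(stretches)
    lateral <- if (axis == 1) 2 else 2
    e_t <- c(0, 0, 0); e_t[lateral] <- 1
    sig <- cauchy_stress(F, params, traction_free_dir = e_t)
    sig[axis, axis]
  }, numeric(1))
  tibble::tibble(lambda = lambda_grid, stress_kpa = stress,
                 direction = direction, tissue_type = params$tissue_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
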