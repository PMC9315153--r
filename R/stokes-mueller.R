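# Stokes / Mueller algebra and the standard optical-element matrices.
#
# Conventions used package-wide (documented once here and in the vignette):
#   * Stokes vector S = (s0, s1, s2, s3): s0 total intensity,
#     s1 = horizontal - vertical, s2 = +45deg - -45deg, s3 = right - left
#     circular. Angles are measured counterclockwise looking toward the
#     source.
#   * A rotated element is M(theta) = R(theta) %*% M %*% R(-theta) with
#     R(theta) the Mueller rotator below.
#   * The ideal waveplate with fast axis at 0 acts on (s2, s3) as
#     [cos d, sin d; -sin d, cos d]; a quarter-wave plate therefore maps
#     (1, 0, 1, 0) to (1, 0, 0, -1).

#' Stokes vector constructor
#'
#' @param s0,s1,s2,s3 Stokes components (arbitrary intensity units).
#' @return Numeric vector of length 4.
#' @export
stokes <- function(s0, s1 = 0, s2 = 0, s3 = 0) {
  c(s0, s1, s2, s3)
}

#' Is a Stokes vector physical?
#'
#' Physical means `s0 >= 0` and `s0^2 >= s1^2 + s2^2 + s3^2` within `tol`.
#'
#' @param S Stokes vector (length-4 numeric).
#' @param tol Numerical tolerance.
#' @return Logical scalar.
#' @export
stokes_is_physical <- function(S, tol = 1e-9) {
  S[1] >= -tol && S[1]^2 + tol >= S[2]^2 + S[3]^2 + S[4]^2 - tol
}

#' Mueller rotator matrix
#'
#' Frame rotation by `angle_deg` (degrees, counterclockwise looking toward
#' the source).
#'
#' @param angle_deg Rotation angle in degrees.
#' @return 4x4 rotation Mueller matrix.
#' @export
mueller_rotator <- function(angle_deg) {
  a <- 2 * angle_deg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  matrix(c(1, 0, 0, 0,
           0, c2, -s2, 0,
           0, s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

rotate_element <- function(M, angle_deg) {
  mueller_rotator(angle_deg) %*% M %*% mueller_rotator(-angle_deg)
}

#' Ideal linear polarizer
#'
#' Normalized so that M11 = 1/2 (unit transmittance for matched input).
#' The result is singular (a projector up to scale).
#'
#' @param axis_deg Transmission-axis angle in degrees.
#' @return 4x4 Mueller matrix.
#' @export
mueller_of_polarizer <- function(axis_deg) {
  M0 <- 0.5 * matrix(c(1, 1, 0, 0,
                       1, 1, 0, 0,
                       0, 0, 0, 0,
                       0, 0, 0, 0), 4, 4, byrow = TRUE)
  rotate_element(M0, axis_deg)
}

#' Ideal linear retarder (waveplate)
#'
#' Determinant 1; leaves s0 unchanged. See the file header for the sign
#' convention (QWP at 0 maps (1,0,1,0) to (1,0,0,-1)).
#'
#' @param retardance_rad Retardance in radians.
#' @param fast_axis_deg Fast-axis angle in degrees.
#' @return 4x4 Mueller matrix.
#' @export
mueller_of_waveplate <- function(retardance_rad, fast_axis_deg = 0) {
  cd <- cos(retardance_rad); sd_ <- sin(retardance_rad)
  M0 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, cd, sd_,
                 0, 0, -sd_, cd), 4, 4, byrow = TRUE)
  rotate_element(M0, fast_axis_deg)
}

#' Linear diattenuator with given diattenuation and axis
#'
#' M11-normalized form: first row (1, D cos 2t, D sin 2t, 0).
#'
#' @param D Diattenuation in `[0, 1]`.
#' @param axis_deg High-transmittance axis angle in degrees.
#' @return 4x4 Mueller matrix.
#' @export
mueller_diattenuator <- function(D, axis_deg = 0) {
  stopifnot(D >= 0, D <= 1)
  a <- sqrt(max(0, 1 - D^2))
  t2 <- 2 * axis_deg * pi / 180
  d <- D * c(cos(t2), sin(t2), 0)
  if (D > 0) {
    dh <- d / D
    mD <- a * diag(3) + (1 - a) * (dh %o% dh)
  } else {
    mD <- diag(3)
  }
  rbind(c(1, d), cbind(d, mD))
}

#' Linear retarder with given retardance and fast axis
#'
#' Same matrix as [mueller_of_waveplate()]; provided under the name used by
#' the decomposition-side code.
#'
#' @inheritParams mueller_of_waveplate
#' @param delta_rad Retardance in radians.
#' @export
mueller_retarder <- function(delta_rad, axis_deg = 0) {
  mueller_of_waveplate(delta_rad, axis_deg)
}

#' Isotropic pure depolarizer
#'
#' Either give the depolarization power `Delta` (block `(1 - Delta) * I`) or
#' the three diagonal depolarization factors `factors`.
#'
#' @param Delta Depolarization in `[0, 1]`.
#' @param factors Optional length-3 diagonal factors (overrides `Delta`).
#' @return 4x4 Mueller matrix.
#' @export
mueller_depolarizer <- function(Delta = NULL, factors = NULL) {
  if (is.null(factors)) {
    stopifnot(!is.null(Delta), Delta >= 0, Delta <= 1)
    factors <- rep(1 - Delta, 3)
  }
  diag(c(1, factors))
}

#' Convert a 2x2 Jones (amplitude) matrix to a Mueller matrix
#'
#' The Jones matrix acts on field components `(E1, E2)` in an orthonormal
#' polarization basis; the Stokes vector in the same basis is
#' `(|E1|^2+|E2|^2, |E1|^2-|E2|^2, 2 Re(E1 E2*), 2 Im(E1 E2*))`.
#'
#' @param J Complex 2x2 matrix.
#' @return Real 4x4 Mueller matrix.
#' @export
jones_to_mueller <- function(J) {
  Tm <- matrix(c(1, 0, 0, 1,
                 1, 0, 0, -1,
                 0, 1, 1, 0,
                 0, -1i, 1i, 0), 4, 4, byrow = TRUE)
  M <- Tm %*% kronecker(J, Conj(J)) %*% solve(Tm)
  Re(M)
}

#' Random physical Mueller matrix
#'
#' Synthesized as a depolarizer-retarder-diattenuator product with parameters
#' drawn uniformly; used for round-trip and property tests.
#'
#' @param D_max,delta_max,Delta_max Upper bounds for the drawn parameters.
#' @return 4x4 Mueller matrix (M11 = 1), with the drawn parameters attached
#'   as attribute `"params"`.
#' @export
random_physical_mueller <- function(D_max = 0.9, delta_max = pi, Delta_max = 0.9) {
  D <- runif(1, 0, D_max)
  delta <- runif(1, 0, delta_max)
  Delta <- runif(1, 0, Delta_max)
  axD <- runif(1, 0, 180)
  axR <- runif(1, 0, 180)
  M <- mueller_depolarizer(Delta) %*% mueller_retarder(delta, axR) %*%
    mueller_diattenuator(D, axD)
  attr(M, "params") <- c(D = D, delta = delta, Delta = Delta,
                         axis_D = axD, axis_R = axR)
  M
}
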