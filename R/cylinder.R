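# Exact scattering by an infinite circular cylinder at oblique incidence
# (classical series solution with Bessel-function boundary conditions),
# angular phase functions, and the single-scattering Mueller matrix used by
# the Monte Carlo transport.
#
# Geometry and notation: the incident direction makes zenith angle zeta with
# the cylinder axis (zeta = 90 degrees is normal incidence); scattered light
# leaves on a cone around the axis, parameterized by the azimuthal scattering
# angle Theta (Theta = 0 forward). The relative refractive index
# m = n_cyl / n_med and the medium wavelength lambda_vac / n_med are used
# throughout. Polarization basis: component 1 ("parallel") lies in the plane
# containing the propagation direction and the cylinder axis, component 2
# ("perpendicular") is orthogonal to it.

#' Cylinder scatterer specification
#'
#' @param radius_nm Cylinder radius in nanometers.
#' @param n_cyl Real refractive index of the cylinder material.
#' @return List of class `"cylinder_spec"`.
#' @export
cylinder_spec <- function(radius_nm, n_cyl = 1.43) {
  stopifnot(radius_nm > 0, n_cyl > 0)
  structure(list(radius_nm = radius_nm, n_cyl = n_cyl),
            class = "cylinder_spec")
}

#' Host medium specification
#'
#' @param n_med Medium refractive index.
#' @param wavelength_nm Vacuum wavelength in nanometers.
#' @param mu_s_per_cm Scattering coefficient in 1/cm.
#' @param thickness_um Slab thickness in micrometers.
#' @return List of class `"medium_spec"`.
#' @export
medium_spec <- function(n_med = 1.35, wavelength_nm = 633,
                        mu_s_per_cm = 200, thickness_um = 6) {
  stopifnot(n_med > 0, wavelength_nm > 0, mu_s_per_cm >= 0, thickness_um > 0)
  structure(list(n_med = n_med, wavelength_nm = wavelength_nm,
                 mu_s_per_cm = mu_s_per_cm, thickness_um = thickness_um),
            class = "medium_spec")
}

#' Size parameter of a cylinder in its host medium
#'
#' `x = 2 pi radius n_med / lambda_vac`.
#'
#' @param spec A [cylinder_spec()].
#' @param med A [medium_spec()].
#' @return Dimensionless size parameter.
#' @export
size_parameter <- function(spec, med) {
  2 * pi * spec$radius_nm * med$n_med / med$wavelength_nm
}

besselH <- function(n, z) complex(real = besselJ(z, n),
                                  imaginary = besselY(z, n))

bessel_dJ <- function(n, z) {
  if (n == 0) return(-besselJ(z, 1))
  (besselJ(z, n - 1) - besselJ(z, n + 1)) / 2
}

bessel_dH <- function(n, z) {
  if (n == 0) return(-besselH(1, z))
  (besselH(n - 1, z) - besselH(n + 1, z)) / 2
}

#' Series coefficients for oblique incidence on an infinite cylinder
#'
#' Cylindrical-harmonic coefficients `a_n^I, b_n^I` (incident E parallel to
#' the axis-incidence plane) and `a_n^II, b_n^II` (perpendicular) for
#' `n = 0 .. N`, truncated at `N = ceil(x + 4 x^(1/3) + 2)` and extended
#' until the trailing coefficients are negligible (relative residual below
#' `1e-12`), otherwise an error with a diagnostic is raised.
#'
#' @param spec A [cylinder_spec()].
#' @param med A [medium_spec()].
#' @param zeta_deg Incidence zenith angle in degrees, in `(0, 90]`.
#' @return List with complex vectors `aI`, `bI`, `aII`, `bII` (index n + 1),
#'   the truncation order `N`, and the size parameter `x`.
#' @export
cylinder_coefficients <- function(spec, med, zeta_deg = 90) {
  stopifnot(zeta_deg > 0, zeta_deg <= 90)
  x <- size_parameter(spec, med)
  m <- spec$n_cyl / med$n_med
  z <- zeta_deg * pi / 180
  xi <- x * sin(z)
  eta <- x * sqrt(m^2 - cos(z)^2)
  N <- ceiling(x + 4 * x^(1 / 3) + 2)

  coef_n <- function(n) {
    Jxi <- besselJ(xi, n); dJxi <- bessel_dJ(n, xi)
    Jeta <- besselJ(eta, n); dJeta <- bessel_dJ(n, eta)
    Hxi <- besselH(n, xi); dHxi <- bessel_dH(n, xi)
    An <- 1i * xi * (xi * dJeta * Jxi - eta * Jeta * dJxi)
    Bn <- xi * (m^2 * xi * dJeta * Jxi - eta * Jeta * dJxi)
    Cn <- n * cos(z) * eta * Jeta * Jxi * (xi^2 / eta^2 - 1)
    Dn <- n * cos(z) * eta * Jeta * Hxi * (xi^2 / eta^2 - 1)
    Vn <- xi * (m^2 * xi * dJeta * Hxi - eta * Jeta * dHxi)
    Wn <- 1i * xi * (eta * Jeta * dHxi - xi * dJeta * Hxi)
    den <- Wn * Vn + 1i * Dn^2
    c(aI = (Cn * Vn - Bn * Dn) / den,
      bI = (Wn * Bn + 1i * Dn * Cn) / den,
      aII = -(An * Vn - 1i * Cn * Dn) / den,
      bII = -1i * (Cn * Wn + An * Dn) / den)
  }

  Nmax <- N + 40
  co <- vapply(0:Nmax, coef_n, complex(4))
  mags <- apply(Mod(co), 2, max)
  # far past convergence the Hankel functions overflow and the coefficient
  # ratios degenerate to NaN; truncate just before the first such order
  bad <- which(!is.finite(mags))
  if (length(bad) > 0) {
    if (bad[1] <= 2) {
      stop(sprintf("cylinder series unstable at x = %.3g, zeta = %.3g deg",
                   x, zeta_deg))
    }
    co <- co[, seq_len(bad[1] - 1), drop = FALSE]
    mags <- mags[seq_len(bad[1] - 1)]
    Nmax <- bad[1] - 2
    N <- min(N, Nmax)
  }
  lead <- max(mags)
  # use the standard truncation order, extended while the tail is still large
  keep <- N
  while (keep < Nmax && mags[keep + 1] > 1e-12 * lead) keep <- keep + 1
  if (mags[keep + 1] > 1e-12 * lead) {
    stop(sprintf(paste0("cylinder series did not converge: x = %.3g, ",
                        "zeta = %.3g deg, trailing/leading = %.3g at N = %d"),
                 x, zeta_deg, mags[keep + 1] / lead, keep))
  }
  list(aI = co[1, 1:(keep + 1)], bI = co[2, 1:(keep + 1)],
       aII = co[3, 1:(keep + 1)], bII = co[4, 1:(keep + 1)],
       N = keep, x = x)
}

amplitudes_from_coefficients <- function(co, Theta_rad) {
  N <- co$N
  n <- 1:N
  cosm <- outer(Theta_rad, n, function(t, k) cos(k * t))
  sinm <- outer(Theta_rad, n, function(t, k) sin(k * t))
  T1 <- co$bI[1] + 2 * as.vector(cosm %*% co$bI[-1])
  T2 <- co$aII[1] + 2 * as.vector(cosm %*% co$aII[-1])
  T3 <- -2i * as.vector(sinm %*% co$aI[-1])
  T4 <- -2i * as.vector(sinm %*% co$bII[-1])
  list(T1 = T1, T2 = T2, T3 = T3, T4 = T4)
}

#' Scattering amplitudes of an infinite cylinder
#'
#' The four elements of the 2x2 amplitude matrix
#' `[[T1, T4], [T3, T2]]` mapping incident `(E_par, E_perp)` to scattered
#' `(E_par, E_perp)` at azimuthal scattering angle `Theta`. The cross terms
#' `T3`, `T4` vanish at normal incidence and are odd in `Theta`.
#'
#' @inheritParams cylinder_coefficients
#' @param Theta_deg Azimuthal scattering angle(s) in degrees.
#' @return List of complex vectors `T1`, `T2`, `T3`, `T4` (same length as
#'   `Theta_deg`).
#' @export
cylinder_amplitudes <- function(spec, med, zeta_deg, Theta_deg) {
  co <- cylinder_coefficients(spec, med, zeta_deg)
  amplitudes_from_coefficients(co, Theta_deg * pi / 180)
}

channel_intensity <- function(amp, mode) {
  switch(mode,
         parallel = Mod(amp$T1)^2 + Mod(amp$T3)^2,
         perpendicular = Mod(amp$T2)^2 + Mod(amp$T4)^2,
         unpolarized = (Mod(amp$T1)^2 + Mod(amp$T3)^2 +
                          Mod(amp$T2)^2 + Mod(amp$T4)^2) / 2)
}

#' Angular phase function of a cylinder population
#'
#' Normalized angular scattering density over the azimuthal angle
#' `Theta in (-180, 180]` (degrees), for unpolarized incidence (average of
#' the parallel and perpendicular channels) or a single channel. The density
#' is per degree and integrates to 1 (trapezoid rule on the periodic grid).
#'
#' @inheritParams cylinder_coefficients
#' @param mode `"unpolarized"`, `"parallel"`, or `"perpendicular"`.
#' @param dtheta_deg Angular grid step in degrees.
#' @return Tibble of class `"phase_function"` with columns `theta_deg`,
#'   `density`, and attributes `zeta_deg`, `mode`, `spec`, `med`.
#' @export
phase_function <- function(spec, med, zeta_deg = 90,
                           mode = c("unpolarized", "parallel",
                                    "perpendicular"),
                           dtheta_deg = 1) {
  mode <- match.arg(mode)
  theta <- seq(-180, 180, by = dtheta_deg)
  amp <- cylinder_amplitudes(spec, med, zeta_deg, theta)
  dens <- channel_intensity(amp, mode)
  # periodic trapezoid: endpoints -180 and 180 coincide
  wts <- rep(dtheta_deg, length(theta))
  wts[c(1, length(theta))] <- dtheta_deg / 2
  dens <- dens / sum(dens * wts)
  out <- tibble::tibble(theta_deg = theta, density = dens)
  attr(out, "zeta_deg") <- zeta_deg
  attr(out, "mode") <- mode
  attr(out, "spec") <- spec
  attr(out, "med") <- med
  class(out) <- c("phase_function", class(out))
  out
}

#' Fraction of scattered light within a forward cone
#'
#' Integral of the phase-function density over `|Theta| <= half_angle`
#' (trapezoid rule with interpolated endpoints).
#'
#' @param pf A [phase_function()].
#' @param half_angle_deg Half angle in degrees, in `(0, 180]`.
#' @return Fraction in `[0, 1]`.
#' @export
forward_fraction <- function(pf, half_angle_deg) {
  stopifnot(half_angle_deg > 0, half_angle_deg <= 180)
  th <- pf$theta_deg
  f <- stats::approxfun(th, pf$density)
  grid <- sort(unique(c(-half_angle_deg, th[th >= -half_angle_deg &
                                              th <= half_angle_deg],
                        half_angle_deg)))
  y <- f(grid)
  min(1, sum(diff(grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' Single-scattering Mueller matrix of a cylinder
#'
#' The 4x4 Mueller matrix at scattering angle `Theta` derived from the 2x2
#' amplitude matrix by the coherency transformation; a pure (non-
#' depolarizing) matrix.
#'
#' @inheritParams cylinder_amplitudes
#' @return 4x4 Mueller matrix (single `Theta_deg` value).
#' @export
single_scatter_mueller <- function(spec, med, zeta_deg, Theta_deg) {
  stopifnot(length(Theta_deg) == 1)
  amp <- cylinder_amplitudes(spec, med, zeta_deg, Theta_deg)
  J <- matrix(c(amp$T1, amp$T3, amp$T4, amp$T2), 2, 2)
  jones_to_mueller(J)
}

#' Acceptance half-angle of an objective
#'
#' `asin(NA / n_immersion)` in degrees: the half-angle of the collection
#' cone corresponding to a numerical aperture.
#'
#' @param na Numerical aperture (0 < na < n_immersion).
#' @param n_immersion Immersion refractive index (1 for dry objectives).
#' @return Half angle in degrees.
#' @export
acceptance_half_angle <- function(na, n_immersion = 1.0) {
  if (na <= 0 || na >= n_immersion) {
    stop("need 0 < NA < n_immersion")
  }
  asin(na / n_immersion) * 180 / pi
}

#' Plot a phase function
#'
#' @param object A `"phase_function"`.
#' @param ... Unused.
#' @return A ggplot of density versus scattering angle.
#' @export
autoplot.phase_function <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$theta_deg, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "azimuthal scattering angle (deg)",
                  y = "density (1/deg)")
}
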