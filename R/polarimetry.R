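# Forward model of the dual-rotating quarter-wave-plate (DRR) polarimeter and
# Mueller matrix reconstruction from the measured intensity series.
#
# The instrument train is P(0) -> QWP(theta) -> sample -> QWP(5 theta) -> P(0),
# i.e. the generator and analyzer retarders rotate at fixed rates 1:5. The
# detected intensity is a trigonometric polynomial in psi = 2 theta with
# harmonics up to n = 12, so 30 equal steps of the generator retarder over
# 180 degrees over-determine the 16 Mueller elements.

psg_stokes <- function(theta_deg) {
  as.numeric(mueller_of_waveplate(pi / 2, theta_deg) %*%
               mueller_of_polarizer(0) %*% c(1, 0, 0, 0))
}

psa_row <- function(theta_deg) {
  as.numeric((mueller_of_polarizer(0) %*%
                mueller_of_waveplate(pi / 2, 5 * theta_deg))[1, ])
}

#' Detected intensity of the dual-rotating-retarder train
#'
#' Intensity at the detector for the generator retarder at `theta_deg` and
#' the analyzer retarder at `5 * theta_deg`, with unpolarized unit-intensity
#' input and ideal elements.
#'
#' @param sample 4x4 sample Mueller matrix.
#' @param theta_deg Generator retarder fast-axis angle, degrees in `[0, 180)`.
#' @return Detected intensity (scalar).
#' @export
drr_intensity <- function(sample, theta_deg) {
  stopifnot(is.matrix(sample), all(dim(sample) == c(4, 4)))
  sum(psa_row(theta_deg) * as.numeric(sample %*% psg_stokes(theta_deg)))
}

#' Simulate a full DRR measurement
#'
#' Generator retarder angles `theta_k = k * span / n_steps` for
#' `k = 0 .. n_steps - 1` (default 30 steps of 6 degrees over 180 degrees;
#' the intensity is periodic in theta with period 180 degrees for ideal
#' elements).
#'
#' @param sample 4x4 sample Mueller matrix.
#' @param n_steps Number of steps; at least 16 are needed to determine the
#'   16 Mueller elements.
#' @param span_deg Angular span covered by the generator retarder.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @return A tibble of class `"intensity_trace"` with columns `step_index`,
#'   `theta_deg`, `intensity`, and attributes `rate_ratio` (= 5) and
#'   `span_deg`.
#' @export
simulate_measurement <- function(sample, n_steps = 30, span_deg = 180,
                                 noise_sd = 0) {
  if (n_steps < 16) {
    stop("n_steps = ", n_steps,
         " leaves the 16 Mueller elements underdetermined; need >= 16")
  }
  theta <- (seq_len(n_steps) - 1) * span_deg / n_steps
  inten <- vapply(theta, function(th) drr_intensity(sample, th), numeric(1))
  if (noise_sd > 0) inten <- inten + rnorm(n_steps, 0, noise_sd)
  out <- tibble::tibble(step_index = seq_len(n_steps) - 1L,
                        theta_deg = theta, intensity = inten)
  attr(out, "rate_ratio") <- 5L
  attr(out, "span_deg") <- span_deg
  class(out) <- c("intensity_trace", class(out))
  out
}

#' Fourier harmonics of an intensity trace
#'
#' Coefficients of `I(psi) = a0 + sum_n (a_n cos(n psi) + b_n sin(n psi))`
#' with `psi = 2 theta`, estimated by the discrete Fourier transform of the
#' uniformly sampled trace. For ideal elements all harmonics above n = 12
#' vanish.
#'
#' @param trace An `intensity_trace`.
#' @param n_max Highest harmonic returned.
#' @return A tibble with columns `n`, `alpha`, `beta` (`beta` is 0 for n = 0).
#' @export
trace_harmonics <- function(trace, n_max = 12) {
  y <- trace$intensity
  n <- length(y)
  stopifnot(n_max <= floor(n / 2))
  f <- fft(y) / n
  alpha <- c(Re(f[1]), 2 * Re(f[2:(n_max + 1)]))
  beta <- c(0, -2 * Im(f[2:(n_max + 1)]))
  tibble::tibble(n = 0:n_max, alpha = alpha, beta = beta)
}

drr_design_matrix <- function(theta_deg) {
  t(vapply(theta_deg, function(th) {
    a <- psa_row(th)
    g <- psg_stokes(th)
    as.numeric(a %o% g)  # entry (i,j) -> coefficient of M[i, j]
  }, numeric(16)))
}

#' Reconstruct a Mueller matrix from a DRR intensity trace
#'
#' `method = "lstsq"` inverts the 30x16 polarimetric measurement matrix built
#' from the known generator/analyzer states by linear least squares.
#' `method = "fourier"` first compresses the trace to its Fourier harmonics
#' (n = 0..12 in psi = 2 theta) and solves the linear system relating the
#' harmonics to the Mueller elements; for ideal settings the two routes agree
#' to machine precision.
#'
#' @param trace An `intensity_trace` from [simulate_measurement()] (or with
#'   the same columns/attributes).
#' @param method `"lstsq"` or `"fourier"`.
#' @return 4x4 Mueller matrix, with the harmonic table attached as attribute
#'   `"harmonics"`.
#' @export
reconstruct_mueller <- function(trace, method = c("lstsq", "fourier")) {
  method <- match.arg(method)
  theta <- trace$theta_deg
  y <- trace$intensity
  A <- drr_design_matrix(theta)
  qa <- qr(A)
  if (qa$rank < 16) {
    stop("polarimetric design matrix is singular (rank ", qa$rank,
         " < 16); the measurement scheme is underdetermined")
  }
  if (method == "lstsq") {
    m <- qr.coef(qa, y)
  } else {
    h <- trace_harmonics(trace)
    hv <- c(h$alpha, h$beta[-1])
    # harmonics of each basis element's intensity trace; exact because the
    # ideal-element intensity is band-limited to n = 12 and the grid resolves
    # harmonics up to floor(n/2) >= 12 for the default 30 steps
    H <- apply(A, 2, function(col) {
      tr <- trace
      tr$intensity <- col
      hh <- trace_harmonics(tr)
      c(hh$alpha, hh$beta[-1])
    })
    qh <- qr(H)
    if (qh$rank < 16) stop("harmonic system is rank deficient")
    m <- qr.coef(qh, hv)
  }
  M <- matrix(m, 4, 4)
  attr(M, "harmonics") <- trace_harmonics(trace)
  M
}
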