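# Polarized photon Monte Carlo through a slab of oriented infinite cylinders
# ("cylinder scattering model"). Photons are launched along +z at a slab of
# thickness `thickness_um`; free paths are exponential with the stated
# scattering coefficient; each scattering event deflects the photon onto the
# specular cone of an individual cylinder whose axis is drawn from a Gaussian
# orientation distribution around the x axis, with the azimuth on the cone
# importance-sampled from the polarized single-scattering intensity.
#
# Reference-frame bookkeeping: each photon carries a unit reference vector
# `ref` orthogonal to its direction; the Stokes vector is expressed in the
# basis (ref, dir x ref). At every event the Stokes vector is rotated into
# the cylinder incidence frame (component 1 in the plane containing direction
# and axis), multiplied by the single-scattering Mueller matrix, and the new
# frame/direction recorded. No absorption: the Stokes vector is renormalized
# so s0 is carried unchanged through every event (weight 1 per photon), so
# transmitted + backscattered (+ terminated) weight equals launched weight
# exactly.

#' Sample an exponential free path
#'
#' Inverse-CDF sampling: `-ln(u) / mu_s`, returned in micrometers.
#'
#' @param mu_s_per_cm Scattering coefficient in 1/cm (> 0).
#' @param u Uniform(0,1) variate(s).
#' @return Free path length(s) in micrometers.
#' @export
sample_free_path <- function(mu_s_per_cm, u) {
  stopifnot(mu_s_per_cm > 0)
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)")
  -log(u) / mu_s_per_cm * 1e4
}

#' Cylinder orientation distribution
#'
#' Mean axis along x; the axis fluctuates by independent Gaussian angles of
#' standard deviation `sd_deg` out of the x-y plane (rotation about y) and
#' within the x-y plane (rotation about z).
#'
#' @param sd_deg Angular standard deviation in degrees (>= 0).
#' @return List of class `"orientation_distribution"`.
#' @export
orientation_distribution <- function(sd_deg = 30) {
  stopifnot(sd_deg >= 0)
  structure(list(sd_deg = sd_deg), class = "orientation_distribution")
}

#' Sample cylinder axes
#'
#' @param dist An [orientation_distribution()].
#' @param n Number of axes to draw.
#' @return `n` x 3 matrix of unit vectors (a plain vector when `n = 1`).
#' @export
sample_orientation <- function(dist, n = 1) {
  s <- dist$sd_deg * pi / 180
  beta <- rnorm(n, 0, s)   # about y: out-of-plane tilt
  alpha <- rnorm(n, 0, s)  # about z: in-plane fluctuation
  v <- cbind(cos(alpha) * cos(beta), sin(alpha) * cos(beta), -sin(beta))
  v <- v / sqrt(rowSums(v^2))
  if (n == 1) as.numeric(v) else v
}

#' Photon state constructor
#'
#' @param pos Position (micrometers, length-3).
#' @param dir Unit direction (length-3).
#' @param ref Unit reference vector orthogonal to `dir` (Stokes component 1
#'   axis).
#' @param S Stokes vector in the (ref, dir x ref) basis.
#' @param n_scatter Scatter count.
#' @return List of class `"photon_state"`.
#' @export
photon_state <- function(pos = c(0, 0, 0), dir = c(0, 0, 1),
                         ref = c(1, 0, 0), S = c(1, 0, 0, 0),
                         n_scatter = 0L) {
  structure(list(pos = pos, dir = dir, ref = ref, S = S,
                 n_scatter = n_scatter, alive = TRUE),
            class = "photon_state")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotate_stokes <- function(S, phi) {
  c2 <- cos(2 * phi); s2 <- sin(2 * phi)
  c(S[1], c2 * S[2] + s2 * S[3], -s2 * S[2] + c2 * S[3], S[4])
}

# angle of target (unit, orthogonal to dir) relative to the (ref, dir x ref)
# frame
frame_angle <- function(target, dir, ref) {
  n <- cross3(dir, ref)
  atan2(sum(target * n), sum(target * ref))
}

mueller_first_row <- function(T1, T2, T3, T4) {
  a1 <- Mod(T1)^2; a2 <- Mod(T2)^2; a3 <- Mod(T3)^2; a4 <- Mod(T4)^2
  z14 <- T1 * Conj(T4); z32 <- T3 * Conj(T2)
  list(M11 = (a1 + a2 + a3 + a4) / 2,
       M12 = (a1 + a3 - a2 - a4) / 2,
       M13 = Re(z14) + Re(z32),
       M14 = -Im(z14) - Im(z32))
}

#' Scattering kernel for a cylinder population
#'
#' Precomputes the azimuthal grid and caches series coefficients per
#' incidence angle (rounded to 0.1 degree) so the Monte Carlo can evaluate
#' single-scattering intensities and Mueller matrices cheaply.
#'
#' @param spec A [cylinder_spec()].
#' @param med A [medium_spec()].
#' @param dtheta_deg Azimuthal sampling grid step in degrees.
#' @return List of class `"cylinder_kernel"` with functions
#'   `grid_amplitudes(zeta_deg)` and `mueller_at(zeta_deg, Theta_deg)`.
#' @export
cylinder_kernel <- function(spec, med, dtheta_deg = 1) {
  theta_grid <- seq(-180 + dtheta_deg / 2, 180 - dtheta_deg / 2,
                    by = dtheta_deg)
  cache <- new.env(parent = emptyenv())
  get_co <- function(zeta_deg) {
    key <- sprintf("%.1f", min(90, max(0.1, zeta_deg)))
    ent <- cache[[key]]
    if (is.null(ent)) {
      co <- cylinder_coefficients(spec, med, as.numeric(key))
      amp <- amplitudes_from_coefficients(co, theta_grid * pi / 180)
      row1 <- mueller_first_row(amp$T1, amp$T2, amp$T3, amp$T4)
      ent <- list(co = co, amp = amp, row1 = row1)
      cache[[key]] <- ent
    }
    ent
  }
  structure(list(
    spec = spec, med = med,
    theta_grid = theta_grid, dtheta_deg = dtheta_deg,
    grid_amplitudes = function(zeta_deg) get_co(zeta_deg),
    mueller_at = function(zeta_deg, Theta_deg) {
      co <- get_co(zeta_deg)$co
      amp <- amplitudes_from_coefficients(co, Theta_deg * pi / 180)
      J <- matrix(c(amp$T1, amp$T3, amp$T4, amp$T2), 2, 2)
      jones_to_mueller(J)
    }
  ), class = "cylinder_kernel")
}

#' One cylinder scattering event
#'
#' Computes the incidence angle from the photon direction and the cylinder
#' axis, draws the azimuth on the specular scattering cone from the
#' polarization-resolved single-scattering intensity (inverse CDF on the
#' kernel grid with in-bin jitter), updates the Stokes vector with the
#' single-scattering Mueller matrix (renormalized so s0 is conserved), and
#' returns the photon with its new direction and reference frame. The
#' outgoing direction honors the cone constraint
#' `angle(out, axis) = angle(in, axis)`.
#'
#' @param photon A [photon_state()].
#' @param axis Unit cylinder-axis vector. If the photon direction is within
#'   1e-9 of the axis the geometry is degenerate and the caller should
#'   resample the axis (an error is raised).
#' @param kernel A [cylinder_kernel()].
#' @return Updated [photon_state()].
#' @export
scatter_event <- function(photon, axis, kernel) {
  stopifnot(photon$alive)
  u <- photon$dir
  ca <- sum(u * axis)
  if (ca < 0) {  # cylinder axes are axial: flip to the incident hemisphere
    axis <- -axis
    ca <- -ca
  }
  if (ca > 1 - 1e-9) stop("degenerate geometry: direction parallel to axis")
  zeta_deg <- acos(min(1, ca)) * 180 / pi

  b1 <- u - ca * axis
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- cross3(axis, b1)

  # incident polarization basis: component 1 in the (dir, axis) plane
  epar_i <- axis - ca * u
  epar_i <- epar_i / sqrt(sum(epar_i^2))
  phi_in <- frame_angle(epar_i, u, photon$ref)
  S1 <- rotate_stokes(photon$S, phi_in)

  ent <- kernel$grid_amplitudes(zeta_deg)
  r1 <- ent$row1
  w <- r1$M11 * S1[1] + r1$M12 * S1[2] + r1$M13 * S1[3] + r1$M14 * S1[4]
  w <- pmax(w, 0)
  k <- sample.int(length(w), 1, prob = w)
  Theta <- kernel$theta_grid[k] + runif(1, -0.5, 0.5) * kernel$dtheta_deg

  M <- kernel$mueller_at(zeta_deg, Theta)
  S2 <- as.numeric(M %*% S1)
  S2 <- S2 * (S1[1] / S2[1])  # no absorption: carry weight unchanged

  sa <- sin(zeta_deg * pi / 180)
  Th <- Theta * pi / 180
  v <- ca * axis + sa * (cos(Th) * b1 + sin(Th) * b2)
  v <- v / sqrt(sum(v^2))
  epar_s <- axis - sum(axis * v) * v
  epar_s <- epar_s / sqrt(sum(epar_s^2))

  photon$dir <- v
  photon$ref <- epar_s
  photon$S <- S2
  photon$n_scatter <- photon$n_scatter + 1L
  photon
}

#' Monte Carlo simulation configuration
#'
#' Defaults follow the study conditions: scattering coefficient 200/cm,
#' 6 um slab, 633 nm light in a medium of index 1.35, cylinder index 1.43,
#' orientation fluctuation 30 degrees, exit binning in 1-degree polar-angle
#' bins over `[0, 90)`.
#'
#' @param spec A [cylinder_spec()].
#' @param med A [medium_spec()].
#' @param orientation An [orientation_distribution()].
#' @param n_photons Photons launched per input polarization state.
#' @param seed RNG seed (integer).
#' @param bin_width_deg Exit polar-angle bin width in degrees.
#' @param n_batches Number of accumulation batches (for bootstrap error
#'   estimates).
#' @param basis `"six"` (H, V, +45, -45, R, L) or `"four"` (minimal) input
#'   states for the per-bin Mueller estimation.
#' @param max_events Event cap per photon; photons exceeding it are recorded
#'   as terminated (bookkept so weight stays conserved).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(spec, med = medium_spec(),
                       orientation = orientation_distribution(30),
                       n_photons = 1e4, seed = 1, bin_width_deg = 1,
                       n_batches = 20, basis = c("six", "four"),
                       max_events = 200) {
  basis <- match.arg(basis)
  stopifnot(n_photons >= 1)
  structure(list(spec = spec, med = med, orientation = orientation,
                 n_photons = as.integer(n_photons), seed = as.integer(seed),
                 bin_width_deg = bin_width_deg,
                 n_batches = as.integer(n_batches), basis = basis,
                 max_events = as.integer(max_events)),
            class = "sim_config")
}

state_basis <- function(basis) {
  S <- cbind(H = c(1, 1, 0, 0), V = c(1, -1, 0, 0),
             P45 = c(1, 0, 1, 0), M45 = c(1, 0, -1, 0),
             R = c(1, 0, 0, 1), L = c(1, 0, 0, -1))
  if (basis == "four") S[, c("H", "V", "P45", "R")] else S
}

#' Run the polarized Monte Carlo
#'
#' Launches `n_photons` per input polarization state along +z, transports
#' them through the slab, and accumulates the exit Stokes vectors of
#' transmitted photons per polar-angle bin (rotated into the fixed detector
#' frame whose component-1 axis is the projection of lab x). Deterministic
#' given the seed.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `"angle_mueller"`: per-bin, per-state, per-batch
#'   Stokes accumulators plus weight ledgers and the configuration.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  kernel <- cylinder_kernel(cfg$spec, cfg$med)
  mu_um <- cfg$med$mu_s_per_cm * 1e-4   # 1/um
  L <- cfg$med$thickness_um
  Sin <- state_basis(cfg$basis)
  n_states <- ncol(Sin)
  n_bins <- ceiling(90 / cfg$bin_width_deg)
  nb <- cfg$n_batches
  S_acc <- array(0, dim = c(n_bins, 4, n_states, nb))
  ball_n <- matrix(0, n_states, nb)
  back_w <- matrix(0, n_states, nb)
  lost_w <- matrix(0, n_states, nb)
  n <- cfg$n_photons
  batch_of <- (seq_len(n) - 1L) %% nb + 1L

  set.seed(cfg$seed)
  for (st in seq_len(n_states)) {
    S0 <- Sin[, st]
    if (mu_um > 0) {
      first <- rexp(n) / mu_um
    } else {
      first <- rep(Inf, n)
    }
    ballistic <- first >= L
    ball_n[st, ] <- tabulate(batch_of[ballistic], nbins = nb)
    for (p in which(!ballistic)) {
      ph <- photon_state(pos = c(0, 0, first[p]), S = S0)
      b <- batch_of[p]
      repeat {
        ax <- sample_orientation(cfg$orientation)
        tries <- 0L
        while (abs(sum(ph$dir * ax)) > 1 - 1e-9 && tries < 100L) {
          ax <- sample_orientation(cfg$orientation)
          tries <- tries + 1L
        }
        if (tries >= 100L) {
          lost_w[st, b] <- lost_w[st, b] + ph$S[1]
          break
        }
        ph <- scatter_event(ph, ax, kernel)
        step <- rexp(1) / mu_um
        znew <- ph$pos[3] + step * ph$dir[3]
        if (ph$dir[3] > 0 && znew >= L) {
          theta_exit <- acos(min(1, ph$dir[3])) * 180 / pi
          bin <- min(n_bins, floor(theta_exit / cfg$bin_width_deg) + 1L)
          e1 <- c(1, 0, 0) - ph$dir[1] * ph$dir
          nrm <- sqrt(sum(e1^2))
          if (nrm < 1e-6) {
            e1 <- c(0, 1, 0) - ph$dir[2] * ph$dir
            nrm <- sqrt(sum(e1^2))
          }
          e1 <- e1 / nrm
          Sdet <- rotate_stokes(ph$S, frame_angle(e1, ph$dir, ph$ref))
          S_acc[bin, , st, b] <- S_acc[bin, , st, b] + Sdet
          break
        }
        if (ph$dir[3] < 0 && znew <= 0) {
          back_w[st, b] <- back_w[st, b] + ph$S[1]
          break
        }
        if (ph$n_scatter >= cfg$max_events) {
          lost_w[st, b] <- lost_w[st, b] + ph$S[1]
          break
        }
        ph$pos <- ph$pos + step * ph$dir
      }
    }
  }
  structure(list(S_acc = S_acc, ball_n = ball_n, back_w = back_w,
                 lost_w = lost_w,
                 launched = rep(n, n_states), Sin = Sin,
                 bin_width_deg = cfg$bin_width_deg, cfg = cfg),
            class = "angle_mueller")
}

#' Weight-conservation ledger of a simulation
#'
#' @param result An `"angle_mueller"` result.
#' @return Tibble with launched, transmitted, backscattered and terminated
#'   weight per input state.
#' @export
conservation <- function(result) {
  trans <- apply(result$S_acc[, 1, , , drop = FALSE], 3, sum) +
    rowSums(result$ball_n)
  tibble::tibble(
    state = colnames(result$Sin),
    launched = result$launched,
    transmitted = trans,
    backscattered = rowSums(result$back_w),
    terminated = rowSums(result$lost_w)
  )
}

acc_to_mueller <- function(Ssum, Sin, launched) {
  Sout <- Ssum / launched[1]  # mean exit Stokes per launched photon, 4 x k
  A <- Sin %*% t(Sin)
  Sout %*% t(Sin) %*% solve(A)
}

#' Angle-resolved or cumulative Mueller matrix from a simulation
#'
#' Least-squares estimate of the 4x4 Mueller matrix mapping the launched
#' input states to the mean exit Stokes vectors of photons in the requested
#' angular range.
#'
#' @param result An `"angle_mueller"` result.
#' @param max_angle_deg Upper polar angle (degrees): cumulative acceptance
#'   cone `[0, max_angle_deg]`.
#' @param min_angle_deg Lower polar angle for an annular ring (default 0).
#' @param include_ballistic Include the unscattered (ballistic) beam, which
#'   exits at exactly 0 degrees with its polarization unchanged. The
#'   angle-resolved scattering analysis excludes it by default, since the
#'   unscattered beam carries no scattering-angle information; include it
#'   when estimating the full transmission Mueller matrix of the slab.
#' @return 4x4 Mueller matrix (per launched photon; `M[1,1]` is the
#'   collected transmitted fraction), or `NULL` if no weight was collected.
#' @export
collected_mueller <- function(result, max_angle_deg, min_angle_deg = 0,
                              include_ballistic = FALSE) {
  bw <- result$bin_width_deg
  bins <- which((seq_len(dim(result$S_acc)[1]) * bw) <= max_angle_deg + 1e-9 &
                  ((seq_len(dim(result$S_acc)[1]) - 1) * bw) >=
                  min_angle_deg - 1e-9)
  if (length(bins) == 0) return(NULL)
  Ssum <- apply(result$S_acc[bins, , , , drop = FALSE], c(2, 3), sum)
  if (include_ballistic && min_angle_deg <= 0) {
    Ssum <- Ssum + result$Sin %*% diag(rowSums(result$ball_n))
  }
  if (sum(Ssum[1, ]) <= 0) return(NULL)
  acc_to_mueller(Ssum, result$Sin, result$launched)
}

#' Diattenuation versus collection angle
#'
#' For `mode = "cumulative"` (default; the high-NA objective also collects
#' the low-NA photons) the Mueller matrix of all photons with exit angle up
#' to each requested angle is formed and its diattenuation reported; for
#' `mode = "annular"` the matrix of each ring between successive requested
#' angles is used.
#'
#' @param result An `"angle_mueller"` result.
#' @param angles_deg Collection angles in degrees.
#' @param mode `"cumulative"` or `"annular"`.
#' @param include_ballistic Passed to [collected_mueller()]; by default the
#'   unscattered beam is excluded from the scattering-angle sweep.
#' @return Tibble with `angle_deg`, `D` (NA where no photons were
#'   collected), and collected `weight`.
#' @export
d_vs_angle <- function(result, angles_deg = seq(5, 55, by = 10),
                       mode = c("cumulative", "annular"),
                       include_ballistic = FALSE) {
  mode <- match.arg(mode)
  lo <- if (mode == "annular") c(0, utils::head(angles_deg, -1)) else
    rep(0, length(angles_deg))
  purrr::map2_dfr(angles_deg, lo, function(a, l) {
    M <- collected_mueller(result, a, l, include_ballistic)
    if (is.null(M)) {
      tibble::tibble(angle_deg = a, D = NA_real_, weight = 0)
    } else {
      tibble::tibble(angle_deg = a, D = diattenuation(M),
                     weight = M[1, 1] * result$launched[1])
    }
  })
}

#' Trend of diattenuation with collection angle, with bootstrap confidence
#'
#' Fits a line to D versus angle and bootstraps the simulation batches to
#' obtain a confidence interval on the slope and on the end-to-end change
#' `D(max angle) - D(min angle)`.
#'
#' @param result An `"angle_mueller"` result.
#' @param angles_deg Collection angles in degrees.
#' @param mode Passed to [d_vs_angle()].
#' @param n_boot Number of bootstrap resamples of the batches.
#' @param seed Seed for the bootstrap resampling.
#' @return List with `d` (the D-vs-angle tibble), `slope`, `slope_ci`,
#'   `dD` (end-to-end change), `dD_ci`, and the bootstrap draws.
#' @export
d_trend <- function(result, angles_deg = seq(5, 55, by = 10),
                    mode = "cumulative", n_boot = 200, seed = 1) {
  d0 <- d_vs_angle(result, angles_deg, mode)
  slope0 <- unname(coef(lm(D ~ angle_deg, data = d0))[2])
  nb <- dim(result$S_acc)[4]
  set.seed(seed)
  draws <- purrr::map_dfr(seq_len(n_boot), function(i) {
    idx <- sample.int(nb, nb, replace = TRUE)
    sub <- result
    sub$S_acc <- result$S_acc[, , , idx, drop = FALSE]
    di <- d_vs_angle(sub, angles_deg, mode)
    tibble::tibble(slope = unname(coef(lm(D ~ angle_deg, data = di))[2]),
                   dD = di$D[nrow(di)] - di$D[1])
  })
  list(d = d0, slope = slope0,
       slope_ci = unname(quantile(draws$slope, c(0.025, 0.975),
                                  na.rm = TRUE)),
       dD = d0$D[nrow(d0)] - d0$D[1],
       dD_ci = unname(quantile(draws$dD, c(0.025, 0.975), na.rm = TRUE)),
       boot = draws)
}
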