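# Seeded synthetic Mueller-matrix images of collagen-like fibrous regions,
# plus the NA/magnification-dependent imaging degradation model. The
# generator composes each pixel as M = M_Delta %*% M_R %*% M_D (the same
# order the polar decomposition inverts), so the per-pixel ground truth
# (D, delta, Delta) is recovered exactly at native resolution.

#' Built-in objective/magnification configurations
#'
#' The five objective settings of the study, with the per-magnification GLCM
#' displacement that compensates the field-of-view differences and the
#' camera pixel pitch.
#'
#' @param labels Optional subset of `c("4x","10x","20x","40x","60x")`.
#' @return Tibble with columns `label`, `mag`, `na`, `glcm_d`,
#'   `camera_pitch_um`, `pixel_pitch_um` (sample-plane pitch).
#' @export
magnification_configs <- function(labels = NULL) {
  cfg <- tibble::tibble(
    label = c("4x", "10x", "20x", "40x", "60x"),
    mag = c(4, 10, 20, 40, 60),
    na = c(0.10, 0.25, 0.40, 0.65, 0.80),
    glcm_d = c(1L, 3L, 5L, 11L, 15L),
    camera_pitch_um = 3.45
  )
  cfg$pixel_pitch_um <- cfg$camera_pitch_um / cfg$mag
  if (!is.null(labels)) cfg <- cfg[match(labels, cfg$label), ]
  cfg
}

#' Mueller image constructor
#'
#' @param m H x W x 4 x 4 numeric array (one Mueller matrix per pixel).
#' @param pixel_pitch_um Sample-plane pixel pitch in micrometers.
#' @param na Objective numerical aperture (NA of the rendering).
#' @param mag Magnification label.
#' @return Array of class `"mueller_image"`.
#' @export
mueller_image <- function(m, pixel_pitch_um, na = NA_real_,
                          mag = NA_character_) {
  stopifnot(is.array(m), length(dim(m)) == 4, all(dim(m)[3:4] == 4))
  attr(m, "pixel_pitch_um") <- pixel_pitch_um
  attr(m, "na") <- na
  attr(m, "mag") <- mag
  class(m) <- c("mueller_image", class(m))
  m
}

#' @export
print.mueller_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("mueller_image %d x %d (pitch %.4g um, NA %s, %s)\n",
              d[1], d[2], attr(x, "pixel_pitch_um"),
              format(attr(x, "na")), format(attr(x, "mag"))))
  invisible(x)
}

gaussian_kernel <- function(sigma_px, max_half = Inf) {
  half <- max(1L, ceiling(3 * sigma_px))
  half <- min(half, max_half)  # truncated (renormalized) on small canvases
  g <- dnorm(-half:half, sd = sigma_px)
  k <- g %o% g
  k / sum(k)
}

blur_plane <- function(plane, sigma_px) {
  if (sigma_px <= 0) return(plane)
  max_half <- floor((min(dim(plane)) - 1) / 2)
  if (max_half < 1) return(plane)
  k <- gaussian_kernel(sigma_px, max_half)
  # EBImage pads with the boundary value ("replicate"), keeping the output
  # a convex combination of input pixels
  as.matrix(EBImage::filter2(plane, k, boundary = "replicate"))
}

#' Generate a synthetic fiber map
#'
#' Fibers are drawn as smooth random strokes (correlated random walks) with
#' a Gaussian cross profile whose width matches the fiber radius. Radii come
#' from a two-component mixture: thin fibers of 100-200 nm and coarse fibers
#' of 1-1.5 um. Density is the clipped sum of the per-fiber profiles,
#' orientation the profile-weighted local tangent (axial, mod pi), and the
#' radius map the profile-weighted mean radius. Deterministic per seed.
#'
#' @param height,width Canvas size in pixels.
#' @param n_fibers Number of fibers (>= 0).
#' @param thin_fraction Probability that a fiber is thin (100-200 nm) rather
#'   than coarse (1-1.5 um).
#' @param mean_orientation_deg Mean fiber direction; `NULL` draws one
#'   uniformly.
#' @param orient_spread_deg SD of each fiber's starting direction around the
#'   mean.
#' @param turn_sd_deg Per-step direction jitter of the random walk.
#' @param pixel_pitch_um Native pixel pitch (defaults to the camera pitch at
#'   60x).
#' @param seed RNG seed.
#' @return List of class `"fiber_map"` with matrices `density` (in `[0,1]`),
#'   `orientation` (radians, mod pi) and `radius_nm`, plus the pitch and
#'   seed.
#' @export
generate_fiber_map <- function(height = 240, width = 240, n_fibers = 30,
                               thin_fraction = 0.5,
                               mean_orientation_deg = NULL,
                               orient_spread_deg = 12, turn_sd_deg = 2.5,
                               pixel_pitch_um = 3.45 / 60, seed = 1) {
  stopifnot(height > 0, width > 0, n_fibers >= 0)
  set.seed(seed)
  if (is.null(mean_orientation_deg)) mean_orientation_deg <- runif(1, 0, 180)
  density <- matrix(0, height, width)
  wsum <- matrix(0, height, width)
  c2 <- matrix(0, height, width)
  s2 <- matrix(0, height, width)
  rsum <- matrix(0, height, width)
  n_steps <- ceiling(1.6 * sqrt(height^2 + width^2))
  for (f in seq_len(n_fibers)) {
    thin <- runif(1) < thin_fraction
    r_nm <- if (thin) runif(1, 100, 200) else runif(1, 1000, 1500)
    sigma_px <- max(0.8, (r_nm / 1000) / pixel_pitch_um)
    th <- (mean_orientation_deg + rnorm(1, 0, orient_spread_deg)) * pi / 180
    pos <- c(runif(1, 1, height), runif(1, 1, width))
    hits_r <- integer(n_steps); hits_c <- integer(n_steps)
    angs <- numeric(n_steps)
    kept <- 0L
    for (s in seq_len(n_steps)) {
      th <- th + rnorm(1, 0, turn_sd_deg * pi / 180)
      pos <- pos + c(sin(th), cos(th))   # row grows along sin, col along cos
      ri <- round(pos[1]); ci <- round(pos[2])
      if (ri >= 1 && ri <= height && ci >= 1 && ci <= width) {
        kept <- kept + 1L
        hits_r[kept] <- ri; hits_c[kept] <- ci; angs[kept] <- th
      }
    }
    if (kept == 0L) next
    idx <- hits_r[1:kept] + (hits_c[1:kept] - 1L) * height
    mask <- matrix(0, height, width)
    mc2 <- matrix(0, height, width)
    ms2 <- matrix(0, height, width)
    for (s in seq_len(kept)) {
      i <- idx[s]
      mask[i] <- mask[i] + 1
      mc2[i] <- mc2[i] + cos(2 * angs[s])
      ms2[i] <- ms2[i] + sin(2 * angs[s])
    }
    bm <- blur_plane(mask, sigma_px)
    pk <- max(bm)
    if (pk <= 0) next
    amp <- 0.85 / pk
    density <- density + amp * bm
    wsum <- wsum + amp * bm
    c2 <- c2 + amp * blur_plane(mc2, sigma_px)
    s2 <- s2 + amp * blur_plane(ms2, sigma_px)
    rsum <- rsum + amp * bm * r_nm
  }
  # FFT-based convolution can leave tiny negative ripple; clip to [0, 1]
  density <- pmin(1, pmax(0, density))
  orientation <- (atan2(s2, c2) / 2) %% pi
  radius <- ifelse(wsum > 1e-12, rsum / wsum, 150)
  structure(list(density = density, orientation = orientation,
                 radius_nm = radius, pixel_pitch_um = pixel_pitch_um,
                 seed = seed,
                 mean_orientation_deg = mean_orientation_deg),
            class = "fiber_map")
}

#' Default optical coefficients of the synthetic tissue
#'
#' Maps of fiber density/orientation/radius to per-pixel polarization
#' parameters: linear retardance `delta = delta_per_density * density`
#' (axis = fiber orientation), diattenuation
#' `D = d_of_radius(radius) * density` (thin fibers carry more
#' diattenuation, mirroring the cylinder phase-function analysis), and
#' depolarization `Delta = Delta_floor + Delta_per_density * density`.
#' Setting `Delta_per_density = 0` decouples depolarization from the fiber
#' density (used as the null generator in correlation tests).
#'
#' @param delta_per_density Retardance (radians) at density 1.
#' @param Delta_floor Baseline depolarization of the background.
#' @param Delta_per_density Density-coupled depolarization.
#' @param d_of_radius Function radius (nm) -> diattenuation coefficient.
#' @return List of class `"fiber_optics"`.
#' @export
fiber_optics <- function(delta_per_density = 1.1,
                         Delta_floor = 0.06,
                         Delta_per_density = 0.25,
                         d_of_radius = function(r_nm)
                           0.02 + 0.10 / (1 + (r_nm / 400)^2)) {
  structure(list(delta_per_density = delta_per_density,
                 Delta_floor = Delta_floor,
                 Delta_per_density = Delta_per_density,
                 d_of_radius = d_of_radius),
            class = "fiber_optics")
}

# compose per-pixel M = M_Delta(Delta) %*% M_R(delta, axis) %*% M_D(D, axis)
# fully vectorized over pixels
compose_mueller_maps <- function(D, delta, Delta, axis) {
  h <- nrow(D); w <- ncol(D)
  if (any(D < 0 | D >= 1) || any(Delta < 0 | Delta >= 1) ||
      any(delta < 0 | delta >= pi)) {
    stop("coefficient ranges violated: need D, Delta in [0,1) and delta in [0,pi)")
  }
  c2 <- cos(2 * axis); s2 <- sin(2 * axis)
  aD <- sqrt(1 - D^2)
  # linear diattenuator blocks
  MD <- array(0, c(h, w, 4, 4))
  MD[, , 1, 1] <- 1
  MD[, , 1, 2] <- MD[, , 2, 1] <- D * c2
  MD[, , 1, 3] <- MD[, , 3, 1] <- D * s2
  MD[, , 2, 2] <- aD + (1 - aD) * c2^2
  MD[, , 2, 3] <- MD[, , 3, 2] <- (1 - aD) * c2 * s2
  MD[, , 3, 3] <- aD + (1 - aD) * s2^2
  MD[, , 4, 4] <- aD
  # linear retarder
  cd <- cos(delta); sd_ <- sin(delta)
  MR <- array(0, c(h, w, 4, 4))
  MR[, , 1, 1] <- 1
  MR[, , 2, 2] <- c2^2 + s2^2 * cd
  MR[, , 2, 3] <- MR[, , 3, 2] <- c2 * s2 * (1 - cd)
  MR[, , 2, 4] <- -s2 * sd_
  MR[, , 3, 3] <- s2^2 + c2^2 * cd
  MR[, , 3, 4] <- c2 * sd_
  MR[, , 4, 2] <- s2 * sd_
  MR[, , 4, 3] <- -c2 * sd_
  MR[, , 4, 4] <- cd
  out <- array(0, c(h, w, 4, 4))
  for (i in 1:4) for (j in 1:4) {
    acc <- matrix(0, h, w)
    for (k in 1:4) acc <- acc + MR[, , i, k] * MD[, , k, j]
    out[, , i, j] <- acc
  }
  a <- 1 - Delta
  for (i in 2:4) for (j in 1:4) out[, , i, j] <- a * out[, , i, j]
  out
}

#' Render a fiber map as a Mueller image
#'
#' Per pixel, `M = M_Delta %*% M_R %*% M_D` with depolarization, retardance
#' and diattenuation taken from the fiber map through the optical
#' coefficients. Decomposing the result recovers the per-pixel ground truth
#' exactly (to numerical precision) at native resolution.
#'
#' @param map A [generate_fiber_map()] result.
#' @param optics A [fiber_optics()] coefficient set.
#' @return A [mueller_image()] at native resolution, with the ground-truth
#'   parameter maps attached as attribute `"truth"`.
#' @export
fiber_map_to_mueller <- function(map, optics = fiber_optics()) {
  rho <- map$density
  D <- optics$d_of_radius(map$radius_nm) * rho
  delta <- optics$delta_per_density * rho
  Delta <- optics$Delta_floor + optics$Delta_per_density * rho
  arr <- compose_mueller_maps(D, delta, Delta, map$orientation)
  img <- mueller_image(arr, map$pixel_pitch_um)
  attr(img, "truth") <- list(D = D, delta = delta, Delta = Delta,
                             axis = map$orientation)
  img
}

#' Degrade a Mueller image to a lower-NA, lower-magnification rendering
#'
#' Each of the 16 element maps is convolved with a shared Gaussian
#' point-spread function of sample-plane sigma `0.21 * lambda / NA` (the
#' standard Gaussian approximation of the widefield Airy core) and then
#' area-averaged to the target sample-plane pixel pitch
#' `camera_pitch / magnification`. Both steps are positive-weight averages,
#' so every output pixel is a convex combination of physical input Mueller
#' matrices and remains physical.
#'
#' @param img A native-resolution [mueller_image()].
#' @param cfg One row of [magnification_configs()].
#' @param lambda_nm Illumination vacuum wavelength.
#' @return A [mueller_image()] at the target pitch with NA/label metadata.
#' @export
degrade_resolution <- function(img, cfg, lambda_nm = 633) {
  stopifnot(inherits(img, "mueller_image"), nrow(cfg) == 1)
  native <- attr(img, "pixel_pitch_um")
  target <- cfg$camera_pitch_um / cfg$mag
  if (target < native - 1e-9) {
    stop("target pitch ", target, " um finer than native ", native, " um")
  }
  sigma_um <- 0.21 * (lambda_nm / 1000) / cfg$na
  sigma_px <- sigma_um / native
  d <- dim(img)
  h <- d[1]; w <- d[2]
  # output pixel owning each native pixel center
  gr <- pmin(floor((seq_len(h) - 0.5) * native / target) + 1L,
             floor(h * native / target + 1e-9))
  gc <- pmin(floor((seq_len(w) - 0.5) * native / target) + 1L,
             floor(w * native / target + 1e-9))
  gr <- pmax(gr, 1L); gc <- pmax(gc, 1L)
  ho <- max(gr); wo <- max(gc)
  out <- array(0, c(ho, wo, 4, 4))
  cnt <- rowsum(matrix(1, h, w), gr)
  cnt <- t(rowsum(t(cnt), gc))
  for (i in 1:4) for (j in 1:4) {
    pl <- blur_plane(unclass(img)[, , i, j], sigma_px)
    pl <- rowsum(pl, gr)
    pl <- t(rowsum(t(pl), gc))
    out[, , i, j] <- pl / cnt
  }
  mueller_image(out, target, na = cfg$na, mag = cfg$label)
}

#' Generate a reproducible set of synthetic tissue regions
#'
#' Independent seeded regions with varied fiber counts, thin/coarse radius
#' mixtures, mean orientations and background depolarization floors,
#' emulating a panel of collagen-rich tissue regions.
#'
#' @param n_regions Number of regions.
#' @param seed Master seed; per-region sub-seeds are drawn from it.
#' @param height,width Canvas size (native pixels).
#' @param coupled If `TRUE` depolarization is coupled to fiber density
#'   (the default generator); if `FALSE` the density-coupled term is 0 and
#'   only the per-region floor varies (null generator).
#' @param optics Base [fiber_optics()] (per-region floors override
#'   `Delta_floor`).
#' @return List of [mueller_image()] objects; each carries its generation
#'   parameters as attribute `"region_params"`.
#' @export
generate_region_set <- function(n_regions = 27, seed = 1, height = 240,
                                width = 240, coupled = TRUE,
                                optics = fiber_optics()) {
  stopifnot(n_regions >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_regions)
  n_fibers <- sample(18:42, n_regions, replace = TRUE)
  thin_frac <- runif(n_regions, 0.3, 0.8)
  orient <- runif(n_regions, 0, 180)
  floors <- runif(n_regions, 0.03, 0.10)
  lapply(seq_len(n_regions), function(r) {
    opt <- optics
    opt$Delta_floor <- floors[r]
    if (!coupled) opt$Delta_per_density <- 0
    fm <- generate_fiber_map(height, width, n_fibers = n_fibers[r],
                             thin_fraction = thin_frac[r],
                             mean_orientation_deg = orient[r],
                             seed = sub_seeds[r])
    img <- fiber_map_to_mueller(fm, opt)
    attr(img, "region_params") <- list(
      region = r, seed = sub_seeds[r], n_fibers = n_fibers[r],
      thin_fraction = thin_frac[r], mean_orientation_deg = orient[r],
      Delta_floor = floors[r], coupled = coupled
    )
    img
  })
}
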