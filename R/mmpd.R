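# Lu-Chipman polar decomposition M = M_Delta %*% M_R %*% M_D and the three
# scalar maps used throughout the study: diattenuation D, linear retardance
# delta, and depolarization Delta.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

pinv3 <- function(A, tol = 1e-12) {
  s <- svd(A)
  d <- ifelse(s$d > tol * max(s$d, tol), 1 / s$d, 0)
  s$v %*% (d * t(s$u))
}

#' Diattenuation of a Mueller matrix
#'
#' `D = sqrt(M12^2 + M13^2 + M14^2) / M11`, clamped to `[0, 1]`. The matrix
#' is normalized by M11 so that D is scale invariant.
#'
#' @param M 4x4 Mueller matrix with `M[1,1] > 0`.
#' @return Diattenuation in `[0, 1]`.
#' @export
diattenuation <- function(M) {
  if (M[1, 1] <= 0) stop("M11 must be positive")
  clamp(sqrt(sum((M[1, 2:4] / M[1, 1])^2)), 0, 1)
}

#' Linear retardance of a retarder Mueller matrix
#'
#' The standard Lu-Chipman magnitude
#' `delta = acos(sqrt((MR22 + MR33)^2 + (MR32 - MR23)^2) - 1)` with indices
#' into the 4x4 retarder matrix (1-based, M11 top-left). The acos argument is
#' clamped to `[-1, 1]`; if clamping exceeds 1e-6 the result carries
#' attribute `"flagged" = TRUE`.
#'
#' @param M_R 4x4 pure-retarder Mueller matrix (e.g. from [lu_chipman()]).
#' @return Linear retardance in radians, in `[0, pi]`.
#' @export
linear_retardance <- function(M_R) {
  arg <- sqrt((M_R[2, 2] + M_R[3, 3])^2 + (M_R[3, 2] - M_R[2, 3])^2) - 1
  out <- acos(clamp(arg, -1, 1))
  if (abs(arg) > 1 + 1e-6) attr(out, "flagged") <- TRUE
  out
}

#' Fast-axis orientation of a linear retarder
#'
#' Extracted from the (4,2) and (4,3) elements; defined modulo pi and
#' returned in `[0, pi)`. Undefined (NA) when the retardance is 0 or pi.
#'
#' @param M_R 4x4 pure-retarder Mueller matrix.
#' @return Axis angle in radians, axial (mod pi).
#' @export
retardance_axis <- function(M_R) {
  s <- M_R[4, 2]; c <- -M_R[4, 3]
  if (s^2 + c^2 < 1e-20) return(NA_real_)
  unname((atan2(s, c) / 2) %% pi)
}

#' Depolarization power of a depolarizer Mueller matrix
#'
#' `Delta = 1 - |tr(M_Delta) - 1| / 3`, clamped to `[0, 1]`.
#'
#' @param M_Delta 4x4 depolarizer matrix (M11 = 1) from [lu_chipman()].
#' @return Depolarization in `[0, 1]`.
#' @export
depolarization <- function(M_Delta) {
  clamp(1 - abs(sum(diag(M_Delta)) - 1) / 3, 0, 1)
}

#' Lu-Chipman polar decomposition
#'
#' Factors an M11-normalized Mueller matrix as
#' `M = M_Delta %*% M_R %*% M_D` (depolarizer, retarder, diattenuator, in
#' that multiplication order). The diattenuator is built from the first row;
#' the depolarizer 3x3 block is the signed principal square root of
#' `m' m'^T` with the sign of `det(m')`; the retarder is what remains.
#'
#' @param M 4x4 Mueller matrix with `M[1,1] > 0`.
#' @param tol Eigenvalue clipping tolerance: eigenvalues of `m' m'^T` in
#'   `(-tol, 0)` are clipped to 0; more negative ones flag the result.
#' @return An object of class `"mmpd"`: a list with the three factor
#'   matrices `M_D`, `M_R`, `M_Delta`, the scalars `D`, `delta`, `Delta`,
#'   the retarder axis `axis` (radians, mod pi), a `flag` string ("" when
#'   clean), and `resid`, the max-abs reconstruction residual
#'   `M_Delta M_R M_D - M/M11`.
#' @export
lu_chipman <- function(M, tol = 1e-9) {
  if (!is.matrix(M) || any(dim(M) != c(4, 4))) stop("M must be 4x4")
  if (M[1, 1] <= 0) stop("M11 must be positive")
  N <- M / M[1, 1]
  flag <- character(0)

  d <- N[1, 2:4]
  D <- sqrt(sum(d^2))
  if (D > 1) {
    if (D > 1 + 1e-6) flag <- c(flag, "D>1")
    d <- d / D
    D <- 1
  }
  a <- sqrt(max(0, 1 - D^2))
  if (D > 0) {
    dh <- d / D
    mD <- a * diag(3) + (1 - a) * (dh %o% dh)
  } else {
    mD <- diag(3)
  }
  M_D <- rbind(c(1, d), cbind(d, mD))

  if (1 - D^2 > 1e-12) {
    MDi <- solve(M_D)
  } else {
    # ideal-polarizer limit: M_D is singular, use the pseudo-inverse
    s <- svd(M_D)
    di <- ifelse(s$d > 1e-12, 1 / s$d, 0)
    MDi <- s$v %*% (di * t(s$u))
    flag <- c(flag, "D~1")
  }
  Mp <- N %*% MDi
  PDelta <- Mp[2:4, 1]
  mp <- Mp[2:4, 2:4]

  C <- mp %*% t(mp)
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -tol)) flag <- c(flag, "negative_eigenvalue")
  lam <- pmax(lam, 0)
  s_det <- if (det(mp) < 0) -1 else 1
  mDelta <- s_det * (e$vectors %*% (sqrt(lam) * t(e$vectors)))
  if (min(sqrt(lam)) > 1e-12 * max(sqrt(lam), 1e-12)) {
    mR <- solve(mDelta, mp)
  } else {
    mR <- pinv3(mDelta) %*% mp
    flag <- c(flag, "singular_depolarizer")
  }
  M_Delta <- rbind(c(1, 0, 0, 0), cbind(PDelta, mDelta))
  M_R <- rbind(c(1, 0, 0, 0), cbind(c(0, 0, 0), mR))

  delta <- linear_retardance(M_R)
  if (isTRUE(attr(delta, "flagged"))) flag <- c(flag, "retardance_clamped")
  out <- list(
    M_D = M_D, M_R = M_R, M_Delta = M_Delta,
    D = D,
    delta = as.numeric(delta),
    Delta = depolarization(M_Delta),
    axis = retardance_axis(M_R),
    flag = paste(flag, collapse = ","),
    resid = max(abs(M_Delta %*% M_R %*% M_D - N))
  )
  class(out) <- "mmpd"
  out
}

#' @export
print.mmpd <- function(x, ...) {
  cat("Lu-Chipman polar decomposition\n")
  cat(sprintf("  D = %.6f  delta = %.6f rad  Delta = %.6f\n",
              x$D, x$delta, x$Delta))
  if (nzchar(x$flag)) cat("  flags:", x$flag, "\n")
  cat(sprintf("  reconstruction residual %.3g\n", x$resid))
  invisible(x)
}

#' Tidy an mmpd result
#'
#' @param x An `"mmpd"` object.
#' @param ... Unused.
#' @return One-row tibble with `D`, `delta`, `Delta`, `axis`, `flag`,
#'   `resid`.
#' @export
tidy.mmpd <- function(x, ...) {
  tibble::tibble(D = x$D, delta = x$delta, Delta = x$Delta,
                 axis = x$axis, flag = x$flag, resid = x$resid)
}

#' Per-pixel polar decomposition of a Mueller image
#'
#' Applies [lu_chipman()] at every pixel of a Mueller image (the hot loop
#' runs in compiled code; the scalar R implementation is the reference) and
#' returns the three parameter maps plus a validity mask. Flagged pixels
#' (clamping beyond tolerance, strongly negative eigenvalues) are marked
#' invalid and excluded from downstream statistics.
#'
#' @param img A `"mueller_image"` (H x W x 4 x 4 array with pixel-pitch/NA
#'   metadata, see [mueller_image()]).
#' @return An object of class `"polar_param_maps"`: list of matrices
#'   `D_map`, `delta_map` (radians), `Delta_map`, logical `valid`, plus
#'   `pixel_pitch_um`, `na`, `mag` copied from the image.
#' @export
decompose_image <- function(img) {
  stopifnot(inherits(img, "mueller_image"))
  dm <- dim(img)
  h <- dm[1]; w <- dm[2]
  if (h * w == 0) stop("empty image")
  X <- matrix(aperm(unclass(img), c(3, 4, 1, 2)), nrow = 16)
  if (any(X[1, ] <= 0)) stop("every pixel must have M11 > 0")
  res <- mmpd_pixels(X)
  out <- list(
    D_map = matrix(res[1, ], h, w),
    delta_map = matrix(res[2, ], h, w),
    Delta_map = matrix(res[3, ], h, w),
    valid = matrix(res[4, ] == 0, h, w),
    pixel_pitch_um = attr(img, "pixel_pitch_um"),
    na = attr(img, "na"),
    mag = attr(img, "mag")
  )
  class(out) <- "polar_param_maps"
  out
}

#' @export
print.polar_param_maps <- function(x, ...) {
  cat(sprintf("polar parameter maps %d x %d (pitch %.4g um, NA %s, %s)\n",
              nrow(x$D_map), ncol(x$D_map), x$pixel_pitch_um,
              format(x$na), format(x$mag)))
  cat(sprintf("  D in [%.3f, %.3f], delta in [%.3f, %.3f] rad, Delta in [%.3f, %.3f]\n",
              min(x$D_map), max(x$D_map), min(x$delta_map), max(x$delta_map),
              min(x$Delta_map), max(x$Delta_map)))
  cat(sprintf("  %d/%d pixels valid\n", sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Tidy polar parameter maps to a long tibble
#'
#' @param x A `"polar_param_maps"` object.
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `D`, `delta`, `Delta`, `valid`.
#' @export
tidy.polar_param_maps <- function(x, ...) {
  h <- nrow(x$D_map); w <- ncol(x$D_map)
  tibble::tibble(
    row = rep(seq_len(h), times = w),
    col = rep(seq_len(w), each = h),
    D = as.numeric(x$D_map),
    delta = as.numeric(x$delta_map),
    Delta = as.numeric(x$Delta_map),
    valid = as.logical(x$valid)
  )
}

#' Plot polar parameter maps
#'
#' @param object A `"polar_param_maps"` object.
#' @param ... Unused.
#' @return A ggplot with one facet per parameter.
#' @export
autoplot.polar_param_maps <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("D", "delta", "Delta"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = c("D", "delta", "Delta")))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
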