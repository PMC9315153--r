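# First-order statistical moments and gray-level co-occurrence (GLCM)
# texture features of parameter images.
#
# Study configuration: parameter images are normalized to gray values
# [0, 255]; GLCM uses Ng = 64 quantized levels and a per-magnification
# inter-pixel displacement d = 1, 3, 5, 11, 15 for 4x, 10x, 20x, 40x, 60x
# (compensating the field-of-view differences). Mean/Entropy are computed on
# the 256-level normalized image, before Ng re-quantization.

#' Normalize a real-valued map to gray values 0..255
#'
#' Affine map of `[lo, hi]` to `[0, 255]`, rounded half-up and clipped.
#' `lo`/`hi` default to the map's own min/max; a constant map under the
#' automatic range maps to all zeros (documented convention, not an error).
#'
#' @param map Numeric matrix.
#' @param lo,hi Range mapped to `[0, 255]`; must satisfy `hi > lo` when
#'   given explicitly.
#' @return Integer matrix of class `"gray_image"` with values in 0..255.
#' @export
normalize_to_gray <- function(map, lo = NULL, hi = NULL) {
  auto <- is.null(lo) || is.null(hi)
  if (is.null(lo)) lo <- min(map)
  if (is.null(hi)) hi <- max(map)
  if (!auto && hi <= lo) stop("hi must be greater than lo")
  if (hi <= lo) {
    g <- matrix(0L, nrow(map), ncol(map))
  } else {
    g <- floor((map - lo) / (hi - lo) * 255 + 0.5)  # round half-up
    g <- matrix(as.integer(pmin(255, pmax(0, g))), nrow(map), ncol(map))
  }
  class(g) <- c("gray_image", class(g))
  g
}

#' First-order moments of a gray image
#'
#' `Mean = sum_i z_i p(z_i)` and `Entropy = -sum_i p(z_i) log2 p(z_i)`
#' (with `0 log 0 := 0`), where p runs over the `levels` gray values.
#'
#' @param img Gray image (integer matrix, values `0 .. levels - 1`).
#' @param levels Number of gray levels (256 for the normalized images).
#' @return Named numeric vector `c(mean = , entropy = )`.
#' @export
first_order_moments <- function(img, levels = 256) {
  v <- as.integer(img)
  if (length(v) == 0) stop("empty image")
  counts <- tabulate(v + 1L, nbins = levels)
  p <- counts / length(v)
  nz <- p > 0
  c(mean = sum((seq_len(levels) - 1) * p),
    entropy = -sum(p[nz] * log2(p[nz])))
}

glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d),
         "45" = c(-d, d),
         "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("direction must be one of 0, 45, 90, 135 degrees"))
}

#' Gray-level co-occurrence matrix
#'
#' Gray values (0..255) are re-quantized to `Ng` uniform bins; pairs of
#' pixels separated by displacement `d` along each direction in `angles`
#' are accumulated symmetrically (both orderings) and pooled over the given
#' direction set, then normalized to sum 1.
#'
#' @param img Gray image (values 0..255).
#' @param d Inter-pixel displacement in pixels (>= 1).
#' @param Ng Number of quantized gray levels (2..256).
#' @param angles Direction set, subset of `c(0, 45, 90, 135)` degrees.
#' @return `Ng` x `Ng` matrix of class `"glcm"` with attributes `Ng`, `d`,
#'   `angles`.
#' @export
compute_glcm <- function(img, d, Ng = 64, angles = c(0, 45, 90, 135)) {
  stopifnot(d >= 1, Ng >= 2, Ng <= 256)
  q <- matrix((as.integer(unclass(img)) * as.integer(Ng)) %/% 256L + 1L,
              nrow(img), ncol(img))
  h <- nrow(q); w <- ncol(q)
  counts <- matrix(0, Ng, Ng)
  any_pairs <- FALSE
  for (ang in angles) {
    off <- glcm_offset(ang, as.integer(d))
    rlo <- max(1L, 1L - off[1]); rhi <- min(h, h - off[1])
    clo <- max(1L, 1L - off[2]); chi <- min(w, w - off[2])
    if (rlo > rhi || clo > chi) next
    r0 <- rlo:rhi
    c0 <- clo:chi
    i <- as.integer(q[r0, c0, drop = FALSE])
    j <- as.integer(q[r0 + off[1], c0 + off[2], drop = FALSE])
    if (length(i) == 0) next
    any_pairs <- TRUE
    tab <- tabulate((j - 1L) * Ng + i, nbins = Ng * Ng)
    counts <- counts + matrix(tab, Ng, Ng)
  }
  if (!any_pairs) {
    stop("image too small for displacement d = ", d,
         " in every requested direction")
  }
  counts <- counts + t(counts)  # symmetric accumulation
  P <- counts / sum(counts)
  attr(P, "Ng") <- Ng
  attr(P, "d") <- d
  attr(P, "angles") <- angles
  class(P) <- c("glcm", class(P))
  P
}

#' Haralick features of a GLCM
#'
#' With level indices `i, j = 1..Ng`:
#' Contrast `= sum_n n^2 sum_{|i-j|=n} p(i,j)`,
#' Correlation `= (sum_ij ij p(i,j) - mu_x mu_y) / (sigma_x sigma_y)`,
#' Energy `= sum p(i,j)^2`, Homogeneity `= sum p(i,j) / (1 + (i-j)^2)`.
#' Correlation is `NA` when `sigma_x * sigma_y = 0` (single-level image).
#'
#' @param P A normalized GLCM from [compute_glcm()].
#' @return One-row tibble with `contrast`, `correlation`, `energy`,
#'   `homogeneity`.
#' @export
glcm_features <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(Ng) * px)
  muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  corr <- if (sx * sy > 0) {
    (sum(i * j * P) - mux * muy) / (sx * sy)
  } else {
    NA_real_
  }
  tibble::tibble(
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + (i - j)^2))
  )
}

#' Texture summary of one parameter map
#'
#' The full per-image texture pipeline: gray normalization, first-order
#' Mean/Entropy on the 256-level image, and GLCM features computed per
#' direction and averaged over the direction set (the common Haralick
#' practice; it removes fiber-orientation bias).
#'
#' @param map Numeric parameter map.
#' @param d GLCM displacement in pixels.
#' @param Ng GLCM gray levels.
#' @param angles GLCM direction set; features are averaged over it.
#' @param lo,hi Gray-normalization range (`NULL` for per-image min-max; for
#'   cross-magnification comparisons use the fixed physical ranges).
#' @return Tibble with columns `statistic` (mean, entropy, contrast,
#'   correlation, energy, homogeneity) and `value`.
#' @export
texture_summary <- function(map, d, Ng = 64, angles = c(0, 45, 90, 135),
                            lo = NULL, hi = NULL) {
  g <- normalize_to_gray(map, lo, hi)
  fo <- first_order_moments(g, 256)
  feats <- purrr::map(angles, function(a) {
    glcm_features(compute_glcm(g, d, Ng, angles = a))
  }) |>
    dplyr::bind_rows() |>
    dplyr::summarise(dplyr::across(dplyr::everything(),
                                   ~ mean(.x, na.rm = FALSE)))
  tibble::tibble(
    statistic = c("mean", "entropy", "contrast", "correlation", "energy",
                  "homogeneity"),
    value = c(fo[["mean"]], fo[["entropy"]], feats$contrast,
              feats$correlation, feats$energy, feats$homogeneity)
  )
}
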