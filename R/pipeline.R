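# End-to-end study orchestration: per-region, per-magnification parameter
# images, texture summaries, box-plot tables and cross-magnification Pearson
# correlation matrices.

#' Study configuration
#'
#' @param n_regions Number of synthetic regions (>= 3 for correlations).
#' @param seed Master RNG seed.
#' @param mags Magnification table ([magnification_configs()] or a subset).
#' @param Ng GLCM gray levels.
#' @param angles GLCM direction set (features averaged over it).
#' @param normalization `"fixed"` (physical ranges: D, Delta in `[0,1]`,
#'   delta in `[0,pi]`; comparable across magnifications, the study default)
#'   or `"auto"` (per-image min-max).
#' @param height,width Native canvas size in pixels.
#' @param coupled Couple depolarization to fiber density in the generator.
#' @return List of class `"study_config"`.
#' @export
study_config <- function(n_regions = 27, seed = 1,
                         mags = magnification_configs(), Ng = 64,
                         angles = c(0, 45, 90, 135),
                         normalization = c("fixed", "auto"),
                         height = 240, width = 240, coupled = TRUE) {
  normalization <- match.arg(normalization)
  stopifnot(nrow(mags) >= 2)
  structure(list(n_regions = n_regions, seed = seed, mags = mags, Ng = Ng,
                 angles = angles, normalization = normalization,
                 height = height, width = width, coupled = coupled),
            class = "study_config")
}

param_range <- function(parameter) {
  switch(parameter,
         D = c(0, 1),
         delta = c(0, pi),
         Delta = c(0, 1))
}

#' Analyze one region across magnifications
#'
#' For each magnification: degrade the native Mueller image, decompose it
#' per pixel, and compute Mean/Entropy plus the GLCM features of each of the
#' D, delta, Delta maps with the magnification-specific displacement.
#' Invalid pixels (flagged decompositions) are excluded by carrying them at
#' the map median before gray normalization.
#'
#' @param img_native Native-resolution [mueller_image()].
#' @param mags Magnification table rows to render.
#' @param cfg A [study_config()] (texture settings are taken from it).
#' @return Tidy tibble: `magnification`, `na`, `parameter`, `statistic`,
#'   `value`.
#' @export
analyze_region <- function(img_native, mags = magnification_configs(),
                           cfg = study_config()) {
  purrr::map_dfr(seq_len(nrow(mags)), function(k) {
    mrow <- mags[k, ]
    low <- degrade_resolution(img_native, mrow)
    maps <- decompose_image(low)
    purrr::map_dfr(c("D", "delta", "Delta"), function(pn) {
      m <- switch(pn, D = maps$D_map, delta = maps$delta_map,
                  Delta = maps$Delta_map)
      if (!all(maps$valid)) {
        m[!maps$valid] <- median(m[maps$valid])
      }
      rng <- if (cfg$normalization == "fixed") param_range(pn) else
        c(NULL, NULL)
      ts <- texture_summary(m, d = mrow$glcm_d, Ng = cfg$Ng,
                            angles = cfg$angles,
                            lo = rng[1], hi = rng[2])
      dplyr::mutate(ts, magnification = mrow$label, na = mrow$na,
                    parameter = pn, .before = 1)
    })
  })
}

#' Pearson correlation matrix of a statistic across magnifications
#'
#' Correlates the per-region vectors of one statistic of one parameter
#' between every pair of magnifications.
#'
#' @param rows Tidy study table (needs `region`, `magnification`,
#'   `parameter`, `statistic`, `value`).
#' @param parameter `"D"`, `"delta"`, or `"Delta"`.
#' @param statistic Statistic to correlate (default `"mean"`).
#' @return Magnification x magnification correlation matrix (unit diagonal;
#'   `NA` rows/columns for zero-variance vectors).
#' @export
pearson_matrix <- function(rows, parameter, statistic = "mean") {
  wide <- rows |>
    dplyr::filter(.data$parameter == !!parameter,
                  .data$statistic == !!statistic) |>
    dplyr::select("region", "magnification", "value") |>
    tidyr::pivot_wider(names_from = "magnification",
                       values_from = "value") |>
    dplyr::arrange(.data$region)
  if (nrow(wide) < 3) stop("need at least 3 regions for correlations")
  X <- as.matrix(wide[, -1])
  sds <- apply(X, 2, sd)
  R <- suppressWarnings(cor(X))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- 1
  R
}

#' Correlation between mean retardance and mean depolarization
#'
#' For each magnification, the Pearson correlation across regions between
#' the chosen statistic of the delta map and of the Delta map.
#'
#' @param rows Tidy study table.
#' @param statistic Statistic to correlate (default `"mean"`).
#' @return Tibble with `magnification` and `r`.
#' @export
delta_Delta_correlation <- function(rows, statistic = "mean") {
  wide <- rows |>
    dplyr::filter(.data$parameter %in% c("delta", "Delta"),
                  .data$statistic == !!statistic) |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "value")
  if (dplyr::n_distinct(wide$region) < 3) {
    stop("need at least 3 regions for correlations")
  }
  out <- wide |>
    dplyr::group_by(.data$magnification) |>
    dplyr::summarise(r = {
      ok <- sd(.data$delta) > 0 && sd(.data$Delta) > 0
      if (ok) cor(.data$delta, .data$Delta) else NA_real_
    }, .groups = "drop")
  out[match(unique(rows$magnification), out$magnification), ]
}

#' Box-plot statistics backing the per-magnification summaries
#'
#' Median, quartiles and 1.5-IQR whiskers of each statistic across regions.
#'
#' @param rows Tidy study table.
#' @return Tibble grouped by magnification, parameter, statistic.
#' @export
box_stats <- function(rows) {
  rows |>
    dplyr::filter(!is.na(.data$value)) |>  # undefined correlations excluded
    dplyr::group_by(.data$magnification, .data$na, .data$parameter,
                    .data$statistic) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$value),
      q1 = quantile(.data$value, 0.25),
      q3 = quantile(.data$value, 0.75),
      lower = max(min(.data$value),
                  quantile(.data$value, 0.25) - 1.5 * stats::IQR(.data$value)),
      upper = min(max(.data$value),
                  quantile(.data$value, 0.75) + 1.5 * stats::IQR(.data$value)),
      .groups = "drop"
    )
}

#' Run the full resolution study
#'
#' Generates the seeded region set, renders and analyzes every region at
#' every configured magnification, and assembles the texture table, the
#' per-parameter cross-magnification correlation matrices and the
#' delta-Delta correlation vector. Fully deterministic per master seed.
#'
#' @param cfg A [study_config()].
#' @return Object of class `"mm_study"`: list with `table` (tidy texture
#'   rows), `box` (box-plot statistics), `cor` (named list of correlation
#'   matrices for D, delta, Delta), `delta_Delta` (tibble), and `config`.
#' @export
run_study <- function(cfg = study_config()) {
  regions <- generate_region_set(cfg$n_regions, seed = cfg$seed,
                                 height = cfg$height, width = cfg$width,
                                 coupled = cfg$coupled)
  tab <- purrr::imap_dfr(regions, function(img, r) {
    dplyr::mutate(analyze_region(img, cfg$mags, cfg), region = r,
                  .before = 1)
  })
  res <- list(
    table = tab,
    box = box_stats(tab),
    cor = list(D = pearson_matrix(tab, "D"),
               delta = pearson_matrix(tab, "delta"),
               Delta = pearson_matrix(tab, "Delta")),
    delta_Delta = delta_Delta_correlation(tab),
    config = cfg
  )
  class(res) <- "mm_study"
  res
}

#' @export
print.mm_study <- function(x, ...) {
  cat(sprintf("Mueller-matrix resolution study: %d regions x %d magnifications\n",
              x$config$n_regions, nrow(x$config$mags)))
  cat("adjacent-magnification correlations of mean delta:",
      paste(sprintf("%.2f", x$cor$delta[cbind(
        seq_len(nrow(x$cor$delta) - 1), seq_len(nrow(x$cor$delta) - 1) + 1)]),
        collapse = ", "), "\n")
  cat("delta-Delta correlation per magnification:",
      paste(sprintf("%s %.2f", x$delta_Delta$magnification,
                    x$delta_Delta$r), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a study result
#'
#' @param x An `"mm_study"`.
#' @param ... Unused.
#' @return The tidy texture table.
#' @export
tidy.mm_study <- function(x, ...) x$table

#' One-row summary of a study result
#'
#' @param x An `"mm_study"`.
#' @param ... Unused.
#' @return Tibble with region/magnification counts and the minimum
#'   adjacent-magnification correlation of mean delta.
#' @export
glance.mm_study <- function(x, ...) {
  Rd <- x$cor$delta
  adj <- Rd[cbind(seq_len(nrow(Rd) - 1), seq_len(nrow(Rd) - 1) + 1)]
  tibble::tibble(
    n_regions = x$config$n_regions,
    n_magnifications = nrow(x$config$mags),
    min_adjacent_r_delta = min(adj),
    min_delta_Delta_r = min(x$delta_Delta$r)
  )
}

#' Box plots of the texture statistics across magnifications
#'
#' @param object An `"mm_study"`.
#' @param parameter Which parameter image to show.
#' @param ... Unused.
#' @return A ggplot faceted by statistic.
#' @export
autoplot.mm_study <- function(object, parameter = "D", ...) {
  df <- dplyr::filter(object$table, .data$parameter == !!parameter,
                      !is.na(.data$value))
  df$magnification <- factor(df$magnification,
                             levels = object$config$mags$label)
  ggplot2::ggplot(df, ggplot2::aes(.data$magnification, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("parameter %s", parameter))
}
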