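# Plain-format exporters for the package's tabular and image results.

#' Export an intensity trace as CSV
#'
#' Columns: `step_index`, `theta_deg`, `intensity`.
#'
#' @param trace An `intensity_trace` from [simulate_measurement()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace[c("step_index", "theta_deg",
                                         "intensity")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a phase function as CSV
#'
#' Two columns: `theta_deg`, `density` (per degree).
#'
#' @param pf A [phase_function()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_phase_function_csv <- function(pf, path) {
  utils::write.csv(as.data.frame(pf[c("theta_deg", "density")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write polar parameter maps as TIFF images with a JSON sidecar
#'
#' The three maps are written as single-channel floating-point TIFFs
#' (`<prefix>_D.tiff`, `<prefix>_delta.tiff`, `<prefix>_Delta.tiff`; delta
#' is stored scaled by 1/pi so values fit the unit TIFF range, as recorded
#' in the sidecar) plus `<prefix>_meta.json` holding the pixel pitch and
#' NA/magnification metadata.
#'
#' @param maps A `"polar_param_maps"` from [decompose_image()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_param_maps <- function(maps, dir, prefix = "region") {
  stopifnot(inherits(maps, "polar_param_maps"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_param_maps needs the jsonlite package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_D.tiff", "_delta.tiff",
                                           "_Delta.tiff", "_meta.json")))
  EBImage::writeImage(EBImage::Image(maps$D_map), paths[1], type = "tiff",
                      bits.per.sample = 32L)
  EBImage::writeImage(EBImage::Image(maps$delta_map / pi), paths[2],
                      type = "tiff", bits.per.sample = 32L)
  EBImage::writeImage(EBImage::Image(maps$Delta_map), paths[3],
                      type = "tiff", bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_pitch_um = maps$pixel_pitch_um, na = maps$na,
         mag = maps$mag, delta_scale = "radians/pi",
         valid_fraction = mean(maps$valid)),
    paths[4], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
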