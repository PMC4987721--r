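#' Write a movie as a multi-page TIFF (one file per channel, frame-major)
#'
#' Frames are rescaled to the unit range expected by TIFF writers; the
#' scale factor is returned so intensities can be restored.
#'
#' @param frames List of numeric matrices.
#' @param path Output file path.
#' @return The intensity scale factor, invisibly.
#' @export
write_movie_tiff <- function(frames, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write TIFF files.")
  }
  hi <- max(vapply(frames, max, numeric(1)), 1e-12)
  tiff::writeTIFF(lapply(frames, function(f) pmin(pmax(f / hi, 0), 1)),
                  path, bits.per.sample = 16L)
  invisible(hi)
}

#' Read a multi-page TIFF into a list of matrices
#'
#' @param path TIFF file path.
#' @return List of numeric matrices (one per frame).
#' @export
read_movie_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to read TIFF files.")
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  lapply(frames, function(f) if (length(dim(f)) == 3L) f[, , 1] else f)
}

#' Read analysis parameters from a YAML file
#'
#' Recognised top-level blocks: `segmentation` ([segmentation_params()]),
#' `thresholds` ([hit_thresholds()]), `pillars` ([pillar_spec()]). Missing
#' blocks fall back to defaults.
#'
#' @param path YAML file path.
#' @return Named list with `segmentation`, `thresholds`, `pillars`.
#' @export
read_params_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  list(
    segmentation = do.call(segmentation_params,
                           raw$segmentation %||% list()),
    thresholds = do.call(hit_thresholds, raw$thresholds %||% list()),
    pillars = do.call(pillar_spec, raw$pillars %||% list()))
}
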