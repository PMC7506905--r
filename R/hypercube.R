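#' Hyperspectral image cubes
#'
#' A `hyper_cube` is one sample's H x W x C intensity array together with its
#' wavelength axis, an opaque sample identifier, a processing-stage tag, and
#' an augmentation-group identifier. The channel axis is always the third
#' (last) array axis, and wavelengths, when present, ascend with channel
#' index. Intensities are stored as doubles but are conceptually 32-bit
#' floats: [write_cube()] encodes them as float32 on disk.
#'
#' The `stage` tag records where the cube sits in the preprocessing chain and
#' may only move forward along
#' `raw -> channel_selected -> log -> normalized -> resized`.
#'
#' @param pixels numeric 3-D array, height x width x channels, nonnegative
#'   for `stage = "raw"`.
#' @param sample_id character scalar identifying the sample.
#' @param wavelengths optional numeric vector of per-channel wavelengths in
#'   nm; length must equal `dim(pixels)[3]`.
#' @param stage processing stage, one of [cube_stages()].
#' @param group_id augmentation-group identifier; a sample and its augmented
#'   variants share it. Defaults to `sample_id`.
#'
#' @return A `hyper_cube` object.
#' @examples
#' cube <- hyper_cube(array(1:24, c(2, 4, 3)), "s1", wavelengths = c(500, 600, 700))
#' dim(cube$pixels)
#' @export
hyper_cube <- function(pixels, sample_id, wavelengths = NULL, stage = "raw",
                       group_id = sample_id) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    abort("`pixels` must be a 3-D array (height x width x channels).",
          class = "hsal_error_validation")
  }
  if (any(dim(pixels) < 1L)) {
    abort("`pixels` must have positive extent on every axis.",
          class = "hsal_error_validation")
  }
  stage <- match.arg(stage, cube_stages())
  if (!is.null(wavelengths)) {
    if (length(wavelengths) != dim(pixels)[3]) {
      abort(sprintf(
        "`wavelengths` has length %d but the cube has %d channels.",
        length(wavelengths), dim(pixels)[3]
      ), class = "hsal_error_validation")
    }
    wavelengths <- as.numeric(wavelengths)
  }
  storage.mode(pixels) <- "double"
  structure(
    list(
      pixels = pixels,
      wavelengths = wavelengths,
      sample_id = as.character(sample_id),
      stage = stage,
      group_id = as.character(group_id)
    ),
    class = "hyper_cube"
  )
}

#' Processing stages of a hyperspectral cube
#'
#' Stages in pipeline order; [advance_stage()] enforces forward-only moves.
#'
#' @return Character vector of stage names.
#' @export
cube_stages <- function() {
  c("raw", "channel_selected", "log", "normalized", "resized")
}

# forward-only stage transition; errors if `to` is not downstream of cube's stage
advance_stage <- function(cube, from, to) {
  stages <- cube_stages()
  if (cube$stage != from) {
    abort(sprintf(
      "cube '%s' is at stage '%s'; this operation expects stage '%s'.",
      cube$sample_id, cube$stage, from
    ), class = "hsal_error_stage")
  }
  if (match(to, stages) < match(from, stages)) {
    abort("stage transitions only move forward along the preprocessing chain.",
          class = "hsal_error_stage")
  }
  cube$stage <- to
  cube
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<hyper_cube '%s'> %d x %d x %d, stage: %s, group: %s\n",
    x$sample_id, d[1], d[2], d[3], x$stage, x$group_id
  ))
  if (!is.null(x$wavelengths)) {
    cat(sprintf("  wavelengths: %.2f..%.2f nm (%d channels)\n",
                min(x$wavelengths), max(x$wavelengths), length(x$wavelengths)))
  }
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$pixels)

is_hyper_cube <- function(x) inherits(x, "hyper_cube")

assert_cube <- function(x, arg = "cube") {
  if (!is_hyper_cube(x)) {
    abort(sprintf("`%s` must be a hyper_cube.", arg),
          class = "hsal_error_validation")
  }
  invisible(x)
}
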