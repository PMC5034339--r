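# PhaseImage: a 2D quantitative phase map with physical metadata.

#' Construct a phase image
#'
#' A phase image holds a 2D map of optical phase delay (radians) together
#' with the pixel size (um/pixel) and the center illumination wavelength
#' (nm) needed to convert spatial phase statistics into scattering
#' parameters.
#'
#' Non-finite pixels are tolerated at construction (files on disk may
#' contain them); every measurement function rejects masks that contain
#' non-finite phase values.
#'
#' @param values Numeric matrix of phase in radians (rows = y, cols = x).
#' @param pixel_size Pixel size in um/pixel; must be positive.
#' @param wavelength Illumination center wavelength in nm (default 552,
#'   the center wavelength of the white-light source assumed throughout).
#' @return An object of class `phase_image`.
#' @export
#' @examples
#' img <- phase_image(matrix(rnorm(64), 8, 8), pixel_size = 0.1)
#' dim(img$values)
phase_image <- function(values, pixel_size, wavelength = 552) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stopf("`pixel_size` must be a single positive number (um/pixel)")
  }
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0) {
    stopf("`wavelength` must be a single positive number (nm)")
  }
  structure(
    list(
      values = values,
      pixel_size = as.numeric(pixel_size),
      wavelength = as.numeric(wavelength)
    ),
    class = "phase_image"
  )
}

#' @export
print.phase_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<phase_image> %d x %d px, %.4g um/px, lambda0 = %g nm\n",
    d[1], d[2], x$pixel_size, x$wavelength
  ))
  fin <- x$values[is.finite(x$values)]
  if (length(fin)) {
    cat(sprintf(
      "  phase range [%.4g, %.4g] rad%s\n",
      min(fin), max(fin),
      if (length(fin) < length(x$values)) {
        sprintf(" (%d non-finite px)", length(x$values) - length(fin))
      } else ""
    ))
  }
  invisible(x)
}

#' @export
dim.phase_image <- function(x) dim(x$values)

is_phase_image <- function(x) inherits(x, "phase_image")

assert_phase_image <- function(x, arg = "image") {
  if (!is_phase_image(x)) stopf("`%s` must be a phase_image object", arg)
  invisible(x)
}
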