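# Gaussian random phase fields with a closed-form anisotropy oracle.
#
# A stationary zero-mean Gaussian random field with Gaussian covariance
# C(r) = sigma^2 exp(-r^2 / a^2) has mean squared phase gradient
# <|grad phi|^2> = -lap C(0) = 4 sigma^2 / a^2 and phase variance
# sigma^2, so the scattering-phase-theorem anisotropy
#   g = 1 - <|grad phi|^2> / (2 k0^2 <dphi^2>) = 1 - 2 / (k0^2 a^2)
# depends on the correlation length a only.  This makes the field a
# ground-truth oracle for every downstream measurement stage.

#' Specification of a Gaussian random phase field
#'
#' @param shape Integer vector `(rows, cols)` in pixels.
#' @param pixel_size Pixel size in um/pixel.
#' @param sigma Phase standard deviation in radians (`sigma = 0` yields a
#'   constant zero field).
#' @param corr_length Gaussian correlation length `a` in um.  Must be at
#'   least `4 * pixel_size`: below that the texture is not resolved and
#'   finite-difference gradient statistics are badly aliased.
#' @param seed Integer seed; the generated field is a deterministic
#'   function of the spec.
#' @return An object of class `grf_spec`.
#' @export
grf_spec <- function(shape, pixel_size, sigma, corr_length, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (length(shape) != 2L || any(shape < 8L)) {
    stopf("`shape` must give two dimensions of at least 8 px")
  }
  if (pixel_size <= 0) stopf("`pixel_size` must be positive")
  if (sigma < 0) stopf("`sigma` must be non-negative")
  if (corr_length < 4 * pixel_size) {
    stopf(
      "corr_length = %.4g um is below 4 pixels (%.4g um): gradient statistics would be aliased",
      corr_length, 4 * pixel_size
    )
  }
  structure(
    list(
      shape = shape, pixel_size = pixel_size, sigma = sigma,
      corr_length = corr_length, seed = as.integer(seed)
    ),
    class = "grf_spec"
  )
}

#' Generate a Gaussian random phase field
#'
#' Samples the field spectrally by circulant embedding on the periodic
#' domain: the wrap-around covariance array is diagonalized by the 2D
#' FFT, complex white noise is coloured by the square root of the
#' eigenvalues, and the real part is kept.  On the torus the field has
#' exactly the target covariance `C(r) = sigma^2 exp(-r^2 / a^2)`; the
#' domain is assumed much larger than `a`, so wrap-around is negligible.
#'
#' @param spec A [grf_spec()].
#' @return A [phase_image()] with the spec's pixel size.
#' @export
#' @examples
#' f <- generate_grf_phase(grf_spec(128, 0.1, sigma = 0.5, corr_length = 0.6))
#' sd(f$values) # close to 0.5
generate_grf_phase <- function(spec) {
  if (!inherits(spec, "grf_spec")) stopf("`spec` must be a grf_spec")
  nr <- spec$shape[1]
  nc <- spec$shape[2]
  if (spec$sigma == 0) {
    return(phase_image(matrix(0, nr, nc), spec$pixel_size))
  }
  # wrap-around distances on the torus, in um
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1))) * spec$pixel_size
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1))) * spec$pixel_size
  r2 <- outer(dr^2, dc^2, `+`)
  covmat <- spec$sigma^2 * exp(-r2 / spec$corr_length^2)
  lambda <- Re(stats::fft(covmat))
  # tiny negative eigenvalues can appear at machine precision
  lambda[lambda < 0] <- 0
  w <- with_seed(spec$seed, {
    matrix(
      complex(
        real = stats::rnorm(nr * nc, sd = sqrt(0.5)),
        imaginary = stats::rnorm(nr * nc, sd = sqrt(0.5))
      ),
      nr, nc
    )
  })
  field <- Re(stats::fft(sqrt(lambda) * w)) * sqrt(2 / (nr * nc))
  phase_image(field, spec$pixel_size)
}

#' Closed-form anisotropy of a Gaussian-correlated phase field
#'
#' For covariance `C(r) = sigma^2 exp(-r^2/a^2)` the mean squared phase
#' gradient is `4 sigma^2 / a^2`, so the anisotropy implied by the
#' scattering-phase theorem is `g = 1 - 2 / (k0^2 a^2)` with
#' `k0 = 2 pi / lambda0` -- independent of `sigma`.
#'
#' @param corr_length Correlation length `a` in um.
#' @param wavelength Illumination wavelength in nm (default 552).
#' @return The anisotropy value (at most 1; can be arbitrarily negative
#'   for short correlation lengths).
#' @export
#' @examples
#' grf_theoretical_g(0.4696, 552) # ~ 0.930
grf_theoretical_g <- function(corr_length, wavelength = 552) {
  if (any(corr_length <= 0)) stopf("`corr_length` must be positive")
  k0 <- wavenumber_um(wavelength)
  1 - 2 / (k0^2 * corr_length^2)
}

#' Correlation length producing a target anisotropy
#'
#' Inverse of [grf_theoretical_g()]: `a = sqrt(2 / (1 - g)) / k0`.
#'
#' @param g_target Target anisotropy, strictly below 1.
#' @param wavelength Illumination wavelength in nm (default 552).
#' @return Correlation length in um.
#' @export
#' @examples
#' corr_length_for_g(0.93, 552) # ~ 0.4696 um
corr_length_for_g <- function(g_target, wavelength = 552) {
  if (any(g_target >= 1)) {
    stopf("`g_target` must be strictly below 1 (g = 1 needs an infinite correlation length)")
  }
  k0 <- wavenumber_um(wavelength)
  sqrt(2 / (1 - g_target)) / k0
}
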