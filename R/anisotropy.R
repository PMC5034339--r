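# Scattering-phase-theorem anisotropy over an ROI, and phase-noise
# propagation into the uncertainty of g.
#
# Over a region r of an unwrapped phase map phi, the theorem gives
#   g = 1 - <|grad phi|^2>_r / (2 k0^2 <dphi^2>_r),
# where <dphi^2> is the phase variance about the ROI mean and
# <|grad phi|^2> the mean squared gradient magnitude.  Both numerator
# and denominator scale as the square of any multiplicative factor on
# phi, so g is invariant under phi -> c * phi: section thickness (which
# scales phase) drops out.

#' Imaging configuration for anisotropy measurements
#'
#' @param wavelength Center illumination wavelength in nm (default 552).
#' @param calibration Monotone non-decreasing function applied to the raw
#'   anisotropy value (system calibration hook); identity by default.
#'   Monotonicity is checked on a probe grid.
#' @param min_pixels Minimum number of pixels an ROI must rasterize to
#'   (default 10000); below this the spatial statistics of stromal
#'   texture are too unstable to report.
#' @return An object of class `imaging_config` with the derived
#'   wavenumber `k0` (rad/um).
#' @export
imaging_config <- function(wavelength = 552, calibration = identity,
                           min_pixels = 10000L) {
  k0 <- wavenumber_um(wavelength)
  if (!is.function(calibration)) stopf("`calibration` must be a function")
  probe <- seq(-1.5, 1, length.out = 101)
  mapped <- vapply(probe, calibration, numeric(1))
  if (any(diff(mapped) < -sqrt(.Machine$double.eps))) {
    stopf("`calibration` must be monotone non-decreasing")
  }
  if (min_pixels < 1) stopf("`min_pixels` must be at least 1")
  structure(
    list(
      wavelength = wavelength, k0 = k0,
      calibration = calibration, min_pixels = as.integer(min_pixels)
    ),
    class = "imaging_config"
  )
}

as_mask <- function(mask, image) {
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(image$values), ncol(image$values))
  }
  if (!is.matrix(mask) || !identical(dim(mask), dim(image$values))) {
    stopf("`mask` must be a logical matrix with the image's dimensions")
  }
  storage.mode(mask) <- "logical"
  mask
}

check_finite_phase <- function(values, mask) {
  if (anyNA(values[mask]) || any(!is.finite(values[mask]))) {
    stopf("masked region contains non-finite phase values; clean or re-acquire the image")
  }
}

#' Phase variance over a masked region
#'
#' Population variance of the phase about the masked mean,
#' `<(phi - <phi>)^2>`, in rad^2.  Invariant under adding a constant to
#' the phase.
#'
#' @param image A [phase_image()].
#' @param mask Logical matrix of included pixels (`NULL` = whole image).
#' @param min_pixels Minimum masked pixel count (default 10000).
#' @return Phase variance in rad^2.
#' @export
phase_variance <- function(image, mask = NULL, min_pixels = 10000L) {
  assert_phase_image(image)
  mask <- as_mask(mask, image)
  n <- sum(mask)
  if (n < min_pixels) {
    stopf("mask has %d pixels, below the minimum of %d", n, min_pixels)
  }
  check_finite_phase(image$values, mask)
  v <- image$values[mask]
  mean((v - mean(v))^2)
}

# Interior mask: pixels whose 4-neighbour central-difference stencil
# stays inside the mask (and image).
interior_mask <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  inner <- matrix(FALSE, nr, nc)
  if (nr < 3 || nc < 3) return(inner)
  i <- 2:(nr - 1)
  j <- 2:(nc - 1)
  inner[i, j] <- mask[i, j] &
    mask[i - 1, j] & mask[i + 1, j] &
    mask[i, j - 1] & mask[i, j + 1]
  inner
}

#' Mean phase-gradient intensity over a masked region
#'
#' Mean of `|grad phi|^2 = (dphi/dx)^2 + (dphi/dy)^2` in rad^2/um^2,
#' with derivatives by central differences scaled by the pixel size.
#' Pixels whose stencil leaves the mask (or image) are excluded rather
#' than estimated one-sided, so the estimator is exact on linear ramps.
#'
#' @inheritParams phase_variance
#' @return Mean squared gradient magnitude in rad^2/um^2.
#' @export
phase_gradient_intensity <- function(image, mask = NULL, min_pixels = 10000L) {
  assert_phase_image(image)
  mask <- as_mask(mask, image)
  if (sum(mask) < min_pixels) {
    stopf("mask has %d pixels, below the minimum of %d", sum(mask), min_pixels)
  }
  inner <- interior_mask(mask)
  if (!any(inner)) {
    stopf("mask has no interior pixels with a full central-difference stencil")
  }
  check_finite_phase(image$values, mask)
  v <- image$values
  h <- image$pixel_size
  nr <- nrow(v)
  nc <- ncol(v)
  gx <- matrix(NA_real_, nr, nc)
  gy <- matrix(NA_real_, nr, nc)
  gx[, 2:(nc - 1)] <- (v[, 3:nc] - v[, 1:(nc - 2)]) / (2 * h)
  gy[2:(nr - 1), ] <- (v[3:nr, ] - v[1:(nr - 2), ]) / (2 * h)
  mean(gx[inner]^2 + gy[inner]^2)
}

#' Anisotropy from phase statistics
#'
#' `g = 1 - f_grad / (2 k0^2 f_var)`, then the configuration's
#' calibration map.  Values below -1 are non-physical for a scattering
#' anisotropy; they are returned (so that pathological inputs remain
#' visible) but flagged with a warning.
#'
#' @param f_grad Mean phase-gradient intensity, rad^2/um^2.
#' @param f_var Phase variance, rad^2; must be positive.
#' @param config An [imaging_config()].
#' @return Anisotropy value (at most 1 before calibration).
#' @export
#' @examples
#' compute_g(18.139, 1, imaging_config()) # ~ 0.930
compute_g <- function(f_grad, f_var, config = imaging_config()) {
  if (!inherits(config, "imaging_config")) stopf("`config` must be an imaging_config")
  if (f_grad < 0) stopf("`f_grad` must be non-negative")
  if (!is.finite(f_var) || f_var <= 0) {
    stopf("anisotropy is undefined for zero phase variance (constant phase region)")
  }
  raw <- 1 - f_grad / (2 * config$k0^2 * f_var)
  if (raw < -1) {
    warnf("raw anisotropy %.4g is below -1 (non-physical); returning it anyway", raw)
  }
  config$calibration(raw)
}

#' Measure anisotropy over a polygonal ROI
#'
#' Rasterizes the ROI, computes phase variance and gradient intensity
#' over it, and combines them into g.
#'
#' @param image A [phase_image()].
#' @param roi A [roi_polygon()].
#' @param config An [imaging_config()]; its `min_pixels` gates the ROI.
#' @return One-row data.frame with columns `patient_id`, `core_id`,
#'   `roi_label`, `f_grad`, `f_var`, `g`, `n_pixels`.
#' @export
measure_roi <- function(image, roi, config = imaging_config()) {
  assert_phase_image(image)
  mask <- rasterize_roi(roi, dim(image$values))
  f_var <- phase_variance(image, mask, min_pixels = config$min_pixels)
  f_grad <- phase_gradient_intensity(image, mask, min_pixels = config$min_pixels)
  data.frame(
    patient_id = roi$patient_id %||% NA_character_,
    core_id = roi$core_id %||% NA_character_,
    roi_label = roi$label %||% NA_character_,
    f_grad = f_grad,
    f_var = f_var,
    g = compute_g(f_grad, f_var, config),
    n_pixels = sum(mask),
    stringsAsFactors = FALSE
  )
}

#' Measure several ROIs on one image
#'
#' @param image A [phase_image()].
#' @param rois List of [roi_polygon()] objects.
#' @param config An [imaging_config()].
#' @return data.frame with one row per ROI (see [measure_roi()]).
#' @export
measure_rois <- function(image, rois, config = imaging_config()) {
  do.call(rbind, lapply(rois, function(r) measure_roi(image, r, config)))
}

#' Propagate background phase noise into an uncertainty on g
#'
#' Splits a tissue-free background phase image into non-overlapping
#' square windows and computes, per window, the mean gradient intensity
#' and the phase variance.  Following the convention that `f1` and `f2`
#' denote the *squares* of these two quantities, the anisotropy deficit
#' is `1 - g = sqrt(f1 / f2) / (2 k0^2)`, and the first-order (delta
#' method) propagation of the window-to-window spreads `Delta f1`,
#' `Delta f2` -- including their covariance, since both statistics are
#' computed from the same pixels and are strongly correlated -- gives
#'
#'   `Delta g = 1 / (2 k0^2) * 1 / (2 sqrt(f1/f2)) *
#'              sqrt(Var f1 / f2^2 + f1^2 Var f2 / f2^4 - 2 f1 Cov / f2^3)`.
#'
#' The result agrees with the Monte-Carlo spread of single-window g
#' values (see the package tests).
#'
#' @param background A [phase_image()] of a tissue-free area.
#' @param window Window side in pixels (default 64).
#' @param config An [imaging_config()].
#' @return Object of class `noise_estimate`: list with `f1`, `delta_f1`,
#'   `f2`, `delta_f2`, `cov_f1_f2`, `delta_g`, `n_windows`, `window`.
#' @export
estimate_delta_g <- function(background, window = 64L, config = imaging_config()) {
  assert_phase_image(background)
  if (window < 8) stopf("`window` must be at least 8 px")
  nr <- nrow(background$values) %/% window
  nc <- ncol(background$values) %/% window
  n_win <- nr * nc
  if (n_win < 20) {
    stopf("background allows only %d non-overlapping %dx%d windows; at least 20 are required",
          n_win, window, window)
  }
  fg <- numeric(n_win)
  fv <- numeric(n_win)
  k <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1
      sub <- background$values[
        ((i - 1) * window + 1):(i * window),
        ((j - 1) * window + 1):(j * window)
      ]
      img <- phase_image(sub, background$pixel_size, background$wavelength)
      fv[k] <- phase_variance(img, min_pixels = 1L)
      fg[k] <- phase_gradient_intensity(img, min_pixels = 1L)
    }
  }
  f1 <- fg^2
  f2 <- fv^2
  out <- list(
    f1 = mean(f1), delta_f1 = stats::sd(f1),
    f2 = mean(f2), delta_f2 = stats::sd(f2),
    cov_f1_f2 = stats::cov(f1, f2),
    n_windows = n_win, window = as.integer(window)
  )
  if (out$f2 == 0) {
    # noiseless constant background: g carries no noise-induced spread
    out$delta_g <- 0
  } else {
    ratio <- out$f1 / out$f2
    var_ratio <- out$delta_f1^2 / out$f2^2 +
      out$f1^2 * out$delta_f2^2 / out$f2^4 -
      2 * out$f1 * out$cov_f1_f2 / out$f2^3
    var_h <- max(var_ratio, 0) / (4 * ratio)
    out$delta_g <- sqrt(var_h) / (2 * config$k0^2)
  }
  structure(out, class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    "<noise_estimate> %d windows of %d px: delta_g = %.3g\n",
    x$n_windows, x$window, x$delta_g
  ))
  invisible(x)
}
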