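# Synthetic tissue-core phase images: low-phase gland lumens surrounded
# by annular stromal ROIs whose texture is a Gaussian random field tuned
# to a target anisotropy.

#' Generate a synthetic tissue-core phase image with stromal ROIs
#'
#' Glands are laid out on a grid of square cells.  Each cell holds an
#' elliptical low-phase gland lumen surrounded by an annular stromal
#' ROI; the cell's texture is an independent Gaussian random field whose
#' correlation length is chosen via [corr_length_for_g()] so that the
#' measured anisotropy over the ROI matches that gland's target.
#'
#' @param g_target Target anisotropy; a single value or one per gland.
#' @param n_glands Number of glands (default 1; a typical core shows a
#'   stromal layer adjoining 5-6 glands).
#' @param pixel_size Pixel size in um/pixel (default 0.1).
#' @param gland_radius Mean gland lumen radius in um (default 5).
#' @param stroma_width Width of the annular stromal ROI in um
#'   (default 4).
#' @param sigma Phase standard deviation of the stromal texture in
#'   radians (default 0.5).
#' @param seed Integer seed.
#' @param wavelength Illumination wavelength in nm (default 552).
#' @param min_roi_pixels Reject geometries whose annular ROI covers
#'   fewer pixels than this (default 10000, matching the measurement
#'   default): below it g is statistically unstable.
#' @return List with `image` (a [phase_image()]) and `rois` (list of
#'   annular [roi_polygon()]s, one per gland).
#' @export
generate_core_image <- function(g_target, n_glands = 1L, pixel_size = 0.1,
                                gland_radius = 5, stroma_width = 4,
                                sigma = 0.5, seed = 1L, wavelength = 552,
                                min_roi_pixels = 10000L) {
  if (any(g_target >= 1)) stopf("`g_target` must be strictly below 1")
  n_glands <- as.integer(n_glands)
  if (n_glands < 1) stopf("`n_glands` must be at least 1")
  g_target <- rep_len(g_target, n_glands)

  r_gland <- gland_radius / pixel_size          # px
  r_inner <- r_gland * 1.15
  r_outer <- r_inner + stroma_width / pixel_size
  roi_px <- pi * (r_outer^2 - r_inner^2)
  if (roi_px < min_roi_pixels) {
    stopf(paste0(
      "annular ROI would cover ~%.0f pixels (< %d): anisotropy statistics ",
      "are unstable; enlarge gland_radius/stroma_width or reduce pixel_size"
    ), roi_px, min_roi_pixels)
  }
  cell <- 2L * ceiling(r_outer * 1.15)          # px per cell side
  n_cols <- ceiling(sqrt(n_glands))
  n_rows <- ceiling(n_glands / n_cols)
  img <- matrix(0, n_rows * cell, n_cols * cell)
  rois <- vector("list", n_glands)

  for (k in seq_len(n_glands)) {
    gi <- (k - 1) %/% n_cols
    gj <- (k - 1) %% n_cols
    a <- corr_length_for_g(g_target[k], wavelength)
    spec <- grf_spec(cell, pixel_size, sigma, a, seed = derive_seed(seed, k))
    block <- generate_grf_phase(spec)$values
    # elliptical gland lumen: near-flat low phase (texture damped out)
    cx <- cell / 2
    cy <- cell / 2
    ecc <- with_seed(derive_seed(seed, 500000L + k), stats::runif(2, c(0.75, 0), c(1, pi)))
    ct <- cos(ecc[2]); st <- sin(ecc[2])
    xs <- matrix(rep(seq_len(cell) - 0.5 - cx, each = cell), cell, cell)
    ys <- matrix(rep(seq_len(cell) - 0.5 - cy, times = cell), cell, cell)
    u <- ct * xs + st * ys
    v <- -st * xs + ct * ys
    inside <- (u / r_gland)^2 + (v / (r_gland * ecc[1]))^2 <= 1
    block[inside] <- 0.02 * block[inside]
    rr <- gi * cell + seq_len(cell)
    cc <- gj * cell + seq_len(cell)
    img[rr, cc] <- block
    rois[[k]] <- annulus_roi(
      center = c(gj * cell + cx, gi * cell + cy),
      r_inner = r_inner, r_outer = r_outer,
      label = sprintf("stroma_%02d", k)
    )
  }
  list(image = phase_image(img, pixel_size, wavelength), rois = rois)
}
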