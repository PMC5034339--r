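# Tile mosaics: grid placement with fractional overlap, feather
# blending in the overlap strips, and core cropping.

#' Construct a tile grid
#'
#' @param tiles List of [phase_image()] tiles, all of the same shape and
#'   pixel size.
#' @param positions Two-column integer matrix of 1-based `(row, col)`
#'   grid indices, one row per tile.
#' @param overlap_fraction Fraction of each tile edge shared with its
#'   neighbour, in `[0, 0.5)`; default 0.10 as used during mosaic
#'   acquisition.
#' @return Object of class `tile_grid`.
#' @export
tile_grid <- function(tiles, positions, overlap_fraction = 0.10) {
  if (!length(tiles)) stopf("`tiles` must be a non-empty list of phase_image objects")
  lapply(tiles, assert_phase_image, arg = "tiles[[i]]")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(tiles) || ncol(positions) != 2) {
    stopf("`positions` must be a (row, col) matrix with one row per tile")
  }
  d0 <- dim(tiles[[1]]$values)
  px0 <- tiles[[1]]$pixel_size
  for (t in tiles) {
    if (!identical(dim(t$values), d0)) stopf("all tiles must have the same shape")
    if (t$pixel_size != px0) stopf("all tiles must have the same pixel size")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 0.5) {
    stopf("`overlap_fraction` must be in [0, 0.5)")
  }
  if (anyDuplicated(positions)) stopf("duplicate grid positions")
  structure(
    list(tiles = tiles, positions = positions, overlap_fraction = overlap_fraction),
    class = "tile_grid"
  )
}

# 1D feather weight profile for a tile edge: ramps linearly from ~0 to 1
# across the overlap width on sides that have a neighbour, flat 1
# elsewhere.  Complementary by construction: for two abutting tiles the
# weights in the strip sum to exactly 1.
feather_profile <- function(n, overlap_px, ramp_low, ramp_high) {
  w <- rep(1, n)
  if (overlap_px > 0) {
    ramp <- (seq_len(overlap_px) - 0.5) / overlap_px
    if (ramp_low) w[seq_len(overlap_px)] <- ramp
    if (ramp_high) w[n - overlap_px + seq_len(overlap_px)] <- rev(ramp)
  }
  w
}

#' Stitch a tile grid into one mosaic
#'
#' Tiles are placed by grid arithmetic (no registration): tile `(i, j)`
#' starts at `(i - 1) * step` rows down, where
#' `step = tile_size - round(overlap_fraction * tile_size)`.
#' Overlapping strips are combined by linear feather blending, so
#' stitching constant tiles of equal value reproduces that constant
#' exactly, and a 0|1 pair ramps linearly across the strip.
#'
#' @param grid A [tile_grid()].
#' @return A [phase_image()] mosaic.
#' @export
stitch_grid <- function(grid) {
  if (!inherits(grid, "tile_grid")) stopf("`grid` must be a tile_grid")
  d <- dim(grid$tiles[[1]]$values)
  ov_r <- round(grid$overlap_fraction * d[1])
  ov_c <- round(grid$overlap_fraction * d[2])
  step_r <- d[1] - ov_r
  step_c <- d[2] - ov_c
  n_rows <- max(grid$positions[, 1])
  n_cols <- max(grid$positions[, 2])
  out_r <- d[1] + (n_rows - 1) * step_r
  out_c <- d[2] + (n_cols - 1) * step_c
  num <- matrix(0, out_r, out_c)
  den <- matrix(0, out_r, out_c)
  for (k in seq_along(grid$tiles)) {
    i <- grid$positions[k, 1]
    j <- grid$positions[k, 2]
    wr <- feather_profile(d[1], ov_r, ramp_low = i > 1, ramp_high = i < n_rows)
    wc <- feather_profile(d[2], ov_c, ramp_low = j > 1, ramp_high = j < n_cols)
    w <- outer(wr, wc)
    rr <- (i - 1) * step_r + seq_len(d[1])
    cc <- (j - 1) * step_c + seq_len(d[2])
    num[rr, cc] <- num[rr, cc] + w * grid$tiles[[k]]$values
    den[rr, cc] <- den[rr, cc] + w
  }
  if (any(den == 0)) {
    warnf("mosaic has %d uncovered pixels (missing tiles); they are set to 0", sum(den == 0))
    den[den == 0] <- 1
  }
  phase_image(num / den, grid$tiles[[1]]$pixel_size, grid$tiles[[1]]$wavelength)
}

#' Crop a square core region from a mosaic
#'
#' @param mosaic A [phase_image()].
#' @param center `(row, col)` center in 1-based pixel indices (default:
#'   mosaic center).
#' @param size Side of the square crop in pixels (default 5000, the
#'   standard core crop; any size is supported).
#' @return A [phase_image()] of exactly `size x size` pixels.  Regions
#'   outside the mosaic are zero-padded with a warning; the padded
#'   fraction is attached as attribute `pad_fraction`.
#' @export
crop_core <- function(mosaic, center = NULL, size = 5000L) {
  assert_phase_image(mosaic)
  size <- as.integer(size)
  if (size < 1) stopf("`size` must be positive")
  d <- dim(mosaic$values)
  if (is.null(center)) center <- ceiling(d / 2)
  r0 <- round(center[1]) - size %/% 2
  c0 <- round(center[2]) - size %/% 2
  out <- matrix(0, size, size)
  rr <- r0 + seq_len(size) - 1
  cc <- c0 + seq_len(size) - 1
  keep_r <- rr >= 1 & rr <= d[1]
  keep_c <- cc >= 1 & cc <= d[2]
  out[keep_r, keep_c] <- mosaic$values[rr[keep_r], cc[keep_c]]
  pad <- 1 - sum(keep_r) * sum(keep_c) / (size * size)
  if (pad > 0) {
    warnf("crop exceeds the mosaic; %.1f%% of the output is zero padding", 100 * pad)
  }
  res <- phase_image(out, mosaic$pixel_size, mosaic$wavelength)
  attr(res, "pad_fraction") <- pad
  res
}
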