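# Polygonal ROIs: construction, JSON and ImageJ formats, rasterization.
#
# Coordinate convention: 0-based pixel indices, x = column, y = row,
# vertices in pixel units.  The center of pixel (row r, col c) sits at
# (x, y) = (c + 0.5, r + 0.5), as in ImageJ; a pixel belongs to the ROI
# iff its center lies inside the polygon under the even-odd rule.

#' Construct a polygonal ROI
#'
#' @param vertices Two-column numeric matrix (x, y) of at least 3
#'   vertices, in 0-based pixel units.
#' @param label Optional ROI label.
#' @param core_id,patient_id Optional identifiers carried into
#'   measurement tables.
#' @param check_simple If `TRUE` (default), reject self-intersecting
#'   polygons.
#' @return Object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, label = NULL, core_id = NULL,
                        patient_id = NULL, check_simple = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3 || !is.numeric(vertices)) {
    stopf("`vertices` must be a numeric matrix with >= 3 rows and columns (x, y)")
  }
  if (anyNA(vertices)) stopf("`vertices` must not contain NA")
  if (abs(polygon_area(vertices)) < .Machine$double.eps) {
    stopf("degenerate polygon: zero area")
  }
  if (check_simple && !is_simple_polygon(vertices)) {
    stopf("polygon is self-intersecting; ROIs must be simple polygons")
  }
  colnames(vertices) <- c("x", "y")
  structure(
    list(
      vertices = vertices, label = label,
      core_id = core_id, patient_id = patient_id
    ),
    class = "roi_polygon"
  )
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf(
    "<roi_polygon> '%s' (%d vertices, area %.1f px^2)\n",
    x$label %||% "", nrow(x$vertices), abs(polygon_area(x$vertices))
  ))
  invisible(x)
}

#' Signed polygon area (shoelace formula)
#'
#' @param vertices Two-column matrix (x, y).
#' @return Signed area in pixel^2 (positive for counter-clockwise order
#'   in a y-down coordinate system the sign flips; use `abs()` for area).
#' @export
polygon_area <- function(vertices) {
  x <- vertices[, 1]
  y <- vertices[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Segment-intersection test over all non-adjacent edge pairs; O(n^2),
# fine for hand-drawn ROI sizes.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (shared vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
      d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
      d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
      d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize an ROI to a binary pixel mask
#'
#' Scanline even-odd fill: for each pixel row, edge crossings with the
#' horizontal line through the pixel centers are computed, sorted, and
#' pixels between alternate crossing pairs are set.  A pixel is included
#' iff its center `(c + 0.5, r + 0.5)` lies inside the polygon.
#'
#' @param roi A [roi_polygon()].
#' @param shape Integer `(rows, cols)` of the target image.
#' @return Logical matrix of dimension `shape`.  If the polygon extends
#'   beyond the image it is clipped with a warning; a polygon fully
#'   outside yields an empty mask with a warning.
#' @export
rasterize_roi <- function(roi, shape) {
  if (!inherits(roi, "roi_polygon")) stopf("`roi` must be a roi_polygon")
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 1)) stopf("`shape` must be (rows, cols)")
  v <- roi$vertices
  if (any(v[, 1] < 0 | v[, 1] > shape[2] | v[, 2] < 0 | v[, 2] > shape[1])) {
    warnf("ROI '%s' extends beyond the %d x %d image; clipping to image bounds",
          roi$label %||% "", shape[1], shape[2])
  }
  mask <- matrix(FALSE, shape[1], shape[2])
  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- v[c(2:n, 1), 1]; y2 <- v[c(2:n, 1), 2]
  keep <- y1 != y2               # horizontal edges never cross a center line
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  if (!length(x1)) {
    warnf("ROI '%s' produced an empty mask", roi$label %||% "")
    return(mask)
  }
  rows <- seq_len(shape[1])
  for (r in rows) {
    yc <- r - 0.5                # pixel-center y for 0-based row r-1
    hit <- (y1 <= yc & yc < y2) | (y2 <= yc & yc < y1)
    if (!any(hit)) next
    xc <- x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
    xc <- sort(xc)
    # crossings come in pairs under the even-odd rule
    for (p in seq(1, length(xc) - 1, by = 2)) {
      lo <- ceiling(xc[p] - 0.5 + 1e-12)            # first col c with c+0.5 > xc[p]
      hi <- ceiling(xc[p + 1] - 0.5 - 1e-12) - 1L   # last col c with c+0.5 < xc[p+1]
      lo <- max(lo, 0L)
      hi <- min(hi, shape[2] - 1L)
      if (lo <= hi) mask[r, (lo + 1):(hi + 1)] <- TRUE
    }
  }
  if (!any(mask)) warnf("ROI '%s' produced an empty mask", roi$label %||% "")
  mask
}

#' Write / read ROI polygons as JSON
#'
#' The JSON document is a list of objects with `label`, `core_id`,
#' `patient_id`, and vertex arrays `x`, `y` (0-based pixel units);
#' vertices round-trip exactly.
#'
#' @param rois List of [roi_polygon()] objects (or a single one).
#' @param path File path.
#' @return `write_roi_json` returns `path` invisibly; `read_roi_json`
#'   returns a list of [roi_polygon()] objects.
#' @export
write_roi_json <- function(rois, path) {
  if (inherits(rois, "roi_polygon")) rois <- list(rois)
  payload <- lapply(rois, function(r) {
    list(
      label = r$label, core_id = r$core_id, patient_id = r$patient_id,
      x = r$vertices[, 1], y = r$vertices[, 2]
    )
  })
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stopf("ROI file not found: %s", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(payload, function(p) {
    roi_polygon(
      cbind(as.numeric(p$x), as.numeric(p$y)),
      label = p$label, core_id = p$core_id, patient_id = p$patient_id
    )
  })
}

#' Read / write an ImageJ `.roi` polygon file
#'
#' Supports the polygon subtype of the binary ImageJ ROI format
#' ("Iout" magic, big-endian header, 16-bit integer vertex coordinates
#' relative to the bounding box).  Coordinates are therefore stored at
#' integer-pixel precision.
#'
#' @param path File path (`.roi`).
#' @param label Optional label for the returned ROI (defaults to the
#'   file name).
#' @return `read_imagej_roi` returns a [roi_polygon()];
#'   `write_imagej_roi` returns `path` invisibly.
#' @export
read_imagej_roi <- function(path, label = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "Iout")) stopf("%s is not an ImageJ ROI file", path)
  readBin(con, "integer", 1, size = 2, endian = "big")  # version
  roi_type <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  readBin(con, "integer", 1, size = 1, signed = FALSE)  # pad
  if (!roi_type %in% c(0L, 2L, 3L)) {
    stopf("unsupported ImageJ ROI type %d (only polygon-like types are supported)", roi_type)
  }
  top <- readBin(con, "integer", 1, size = 2, endian = "big")
  left <- readBin(con, "integer", 1, size = 2, endian = "big")
  readBin(con, "integer", 2, size = 2, endian = "big")  # bottom, right
  n <- readBin(con, "integer", 1, size = 2, endian = "big")
  if (n < 3) stopf("ImageJ ROI in %s has fewer than 3 vertices", path)
  seek(con, 64)
  xs <- readBin(con, "integer", n, size = 2, endian = "big")
  ys <- readBin(con, "integer", n, size = 2, endian = "big")
  roi_polygon(cbind(left + xs, top + ys),
              label = label %||% sub("\\.roi$", "", basename(path)))
}

#' @rdname read_imagej_roi
#' @param roi A [roi_polygon()]; vertices are rounded to integers.
#' @export
write_imagej_roi <- function(roi, path) {
  if (!inherits(roi, "roi_polygon")) stopf("`roi` must be a roi_polygon")
  v <- round(roi$vertices)
  left <- min(v[, 1]); top <- min(v[, 2])
  right <- max(v[, 1]); bottom <- max(v[, 2])
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL, useBytes = TRUE)
  writeBin(227L, con, size = 2, endian = "big")            # version
  writeBin(as.raw(c(0, 0)), con)                           # type = 0 (polygon), pad
  writeBin(as.integer(c(top, left, bottom, right)), con, size = 2, endian = "big")
  writeBin(as.integer(nrow(v)), con, size = 2, endian = "big")
  writeBin(raw(64 - 18), con)                              # rest of header
  writeBin(as.integer(v[, 1] - left), con, size = 2, endian = "big")
  writeBin(as.integer(v[, 2] - top), con, size = 2, endian = "big")
  invisible(path)
}

#' Read all ROIs from an ImageJ ROI `.zip` archive
#'
#' @param path Path to a zip of `.roi` files.
#' @return List of [roi_polygon()] objects.
#' @export
read_imagej_roi_zip <- function(path) {
  tmp <- tempfile("roizip")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- utils::unzip(path, exdir = tmp)
  lapply(sort(files[grepl("\\.roi$", files)]), read_imagej_roi)
}

#' Annulus ROI as a simple "keyhole" polygon
#'
#' Builds a single simple polygon tracing the outer circle
#' counter-clockwise and the inner circle back clockwise, with the two
#' bridge edges at slightly different angles so the polygon does not
#' self-intersect.  Under the even-odd rasterization rule the enclosed
#' region is the annulus (minus a one-segment sliver at the slit).
#'
#' @param center `(x, y)` center in pixel units.
#' @param r_inner,r_outer Radii in pixels, `0 < r_inner < r_outer`.
#' @param n_vertices Vertices per circle (default 72).
#' @param ... Passed to [roi_polygon()] (label, ids).
#' @return A [roi_polygon()].
#' @export
annulus_roi <- function(center, r_inner, r_outer, n_vertices = 72, ...) {
  if (r_inner <= 0 || r_outer <= r_inner) stopf("need 0 < r_inner < r_outer")
  slit <- 2 * pi / (8 * n_vertices)
  th_out <- seq(slit, 2 * pi - slit, length.out = n_vertices)
  th_in <- seq(2 * pi - 2 * slit, 2 * slit, length.out = n_vertices)
  v <- rbind(
    cbind(center[1] + r_outer * cos(th_out), center[2] + r_outer * sin(th_out)),
    cbind(center[1] + r_inner * cos(th_in), center[2] + r_inner * sin(th_in))
  )
  roi_polygon(v, check_simple = FALSE, ...)
}
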