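# Independent brute-force oracles used across the suite.  These are
# deliberately written as naive loops, separate from the package's
# vectorized implementations.

# Even-odd point-in-polygon by explicit per-point ray casting.
bf_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      x_cross <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      if (px < x_cross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force mask: test every pixel center on a small grid.
bf_rasterize <- function(vertices, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      mask[r, c] <- bf_point_in_polygon(c - 0.5, r - 0.5,
                                        vertices[, 1], vertices[, 2])
    }
  }
  mask
}

# AUC by explicit pair counting, ties worth 1/2.
bf_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Biochemical-recurrence label by scanning every suffix of the series.
bf_bcr <- function(values) {
  n <- length(values)
  for (i in seq_len(n)) {
    if (values[i] >= 0.4) return(TRUE)
    if (values[i] >= 0.2 && i < n) {
      increasing <- TRUE
      for (k in i:(n - 1)) {
        if (values[k + 1] <= values[k]) {
          increasing <- FALSE
          break
        }
      }
      if (increasing) return(TRUE)
    }
  }
  FALSE
}

# Hand product-limit estimator (deaths before censorings at ties).
hand_km <- function(times, events) {
  ut <- sort(unique(times[as.logical(events)]))
  s <- 1
  out <- data.frame(time = ut, survival = NA_real_)
  for (k in seq_along(ut)) {
    at_risk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & as.logical(events))
    s <- s * (1 - d / at_risk)
    out$survival[k] <- s
  }
  out
}

# Convenience: anisotropy of a full image (or mask) in one call.
measure_g <- function(image, mask = NULL, wavelength = 552) {
  cfg <- imaging_config(wavelength = wavelength, min_pixels = 1L)
  compute_g(
    phase_gradient_intensity(image, mask, min_pixels = 1L),
    phase_variance(image, mask, min_pixels = 1L),
    cfg
  )
}
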