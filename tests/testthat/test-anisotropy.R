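# Scattering-phase-theorem statistics and noise propagation.

test_that("phase variance matches hand-computed cases", {
  img <- phase_image(matrix(2.5, 64, 64), 0.1)
  expect_equal(phase_variance(img, min_pixels = 1), 0)

  # half the mask at 0, half at pi: variance (pi/2)^2
  v <- matrix(rep(c(0, pi), each = 32 * 64), 64, 64)
  expect_equal(phase_variance(phase_image(v, 0.1), min_pixels = 1),
               (pi / 2)^2, tolerance = 1e-12)

  # full-period sinusoid of amplitude A: variance A^2/2
  n <- 1000
  x <- (seq_len(n) - 0.5) / n
  s <- matrix(rep(1.3 * sin(2 * pi * x * 4), each = 8), 8, n)
  expect_equal(phase_variance(phase_image(s, 0.1), min_pixels = 1),
               1.3^2 / 2, tolerance = 1e-3)
})

test_that("phase variance and gradient reject tiny or non-finite masks", {
  img <- phase_image(matrix(rnorm(100), 10, 10), 0.1)
  expect_error(phase_variance(img, min_pixels = 10000), "100 pixels")
  bad <- phase_image(matrix(c(NaN, rnorm(99)), 10, 10), 0.1)
  expect_error(phase_variance(bad, min_pixels = 1), "non-finite")
  expect_error(phase_gradient_intensity(bad, min_pixels = 1), "non-finite")
  # a 2-px-wide mask has no interior stencil pixels
  mask <- matrix(FALSE, 10, 10); mask[1:2, ] <- TRUE
  expect_error(phase_gradient_intensity(img, mask, min_pixels = 1), "interior")
})

test_that("gradient intensity is exact on ramps and accurate on sinusoids", {
  h <- 0.05
  n <- 200
  expect_equal(phase_gradient_intensity(phase_image(matrix(7, n, n), h),
                                        min_pixels = 1), 0)
  # linear ramp of slope s rad/um: central differences are exact
  s <- 0.8
  ramp <- matrix(rep(s * h * (seq_len(n) - 1), each = n), n, n)
  expect_equal(phase_gradient_intensity(phase_image(ramp, h), min_pixels = 1),
               s^2, tolerance = 1e-10)
  # sinusoid A sin(2 pi x / L) over full periods: mean |grad|^2 = A^2 (2 pi/L)^2 / 2
  A <- 0.6; L <- 2.5  # um
  nx <- 1000  # 20 full periods of 50 px
  x <- h * (seq_len(nx) - 1)
  sin_img <- phase_image(matrix(rep(A * sin(2 * pi * x / L), each = 64), 64, nx), h)
  expect_equal(phase_gradient_intensity(sin_img, min_pixels = 1),
               A^2 * (2 * pi / L)^2 / 2, tolerance = 0.01)
})

test_that("compute_g reproduces its closed-form examples", {
  cfg <- imaging_config(552)
  expect_equal(compute_g(0, 1, cfg), 1)
  expect_equal(compute_g(18.139, 1, cfg), 0.930, tolerance = 1e-3)
  expect_error(compute_g(1, 0, cfg), "zero phase variance")
  expect_warning(g <- compute_g(1000, 1, cfg), "non-physical")
  expect_lt(g, -1)
})

test_that("sinusoid of period Lambda gives g = 1 - (lambda0/Lambda)^2 / 2", {
  h <- 0.02
  L <- 5.52  # um; lambda0/Lambda = 0.1 so g = 0.995
  nx <- 2760  # 10 full periods
  x <- h * (seq_len(nx) - 1)
  img <- phase_image(matrix(rep(0.7 * sin(2 * pi * x / L), each = 32), 32, nx), h)
  expect_equal(measure_g(img), 0.995, tolerance = 1e-3)
  # any amplitude: scale invariance makes g identical
  img2 <- phase_image(3 * img$values, h)
  expect_equal(measure_g(img2), measure_g(img), tolerance = 1e-12)
})

test_that("g is invariant to phase scaling, offsets, and 90-degree rotation", {
  f <- generate_grf_phase(grf_spec(256, 0.1, 0.4, 0.5, seed = 21))
  g0 <- measure_g(f)
  for (c in c(-3, 0.5, 17)) {
    expect_equal(measure_g(phase_image(c * f$values, 0.1)), g0, tolerance = 1e-10)
  }
  expect_equal(measure_g(phase_image(f$values + 4.2, 0.1)), g0, tolerance = 1e-9)
  expect_equal(measure_g(phase_image(t(f$values), 0.1)), g0, tolerance = 1e-10)
})

test_that("measured g matches the GRF oracle across correlation lengths", {
  # 0.08 um/px keeps a = 0.4 um at 5 px, within the estimator's accuracy range
  for (a in c(0.4, 0.6)) {
    g_hat <- mean(vapply(1:3, function(s) {
      measure_g(generate_grf_phase(grf_spec(512, 0.08, 0.5, a, seed = s)))
    }, numeric(1)))
    expect_equal(g_hat, grf_theoretical_g(a), tolerance = 0.01)
  }
})

test_that("measure_roi composes rasterization and the phase statistics", {
  core <- generate_core_image(0.93, seed = 8)
  m <- measure_roi(core$image, core$rois[[1]])
  expect_equal(m$g, 0.93, tolerance = 0.015)
  expect_gte(m$n_pixels, 10000)
  expect_equal(m$roi_label, "stroma_01")
  # constant region: variance 0, measurement must fail loudly
  flat <- phase_image(matrix(1, 300, 300), 0.1)
  roi <- roi_polygon(cbind(c(10, 290, 290, 10), c(10, 10, 290, 290)))
  expect_error(measure_roi(flat, roi), "zero phase variance")
})

test_that("delta_g is zero for a noiseless background and needs 20 windows", {
  flat <- phase_image(matrix(0, 320, 320), 0.1)
  ne <- estimate_delta_g(flat, window = 64)
  expect_identical(ne$delta_g, 0)
  expect_error(estimate_delta_g(phase_image(matrix(0, 128, 128), 0.1), window = 64),
               "at least 20")
})

test_that("propagated delta_g matches a Monte-Carlo estimate within 15%", {
  sd_noise <- 0.05
  bg <- with(list(), {
    set.seed(101)
    phase_image(matrix(rnorm(768 * 768, sd = sd_noise), 768, 768), 0.1)
  })
  ne <- estimate_delta_g(bg, window = 64)
  set.seed(202)
  g_mc <- replicate(600, {
    w <- phase_image(matrix(rnorm(64 * 64, sd = sd_noise), 64, 64), 0.1)
    measure_g(w)
  })
  expect_equal(ne$delta_g, sd(g_mc), tolerance = 0.15)
})

test_that("more windows stabilize the delta_g estimate", {
  sd_noise <- 0.05
  est <- function(n_side, seed) {
    set.seed(seed)
    bg <- phase_image(matrix(rnorm((64 * n_side)^2, sd = sd_noise),
                             64 * n_side, 64 * n_side), 0.1)
    estimate_delta_g(bg, window = 64)$delta_g
  }
  few <- vapply(1:6, function(s) est(5, s), numeric(1))    # 25 windows
  many <- vapply(1:6, function(s) est(12, s + 50), numeric(1))  # 144 windows
  expect_lt(sd(many), sd(few))
})

test_that("calibration hook is applied and must be monotone", {
  cfg <- imaging_config(calibration = function(g) 0.5 * g + 0.4)
  expect_equal(compute_g(0, 1, cfg), 0.9)
  expect_error(imaging_config(calibration = function(g) -g), "monotone")
})
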