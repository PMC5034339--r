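# Phase TIFF + sidecar round trips, ROI formats, rasterization.

test_that("phase TIFF round-trips bit-exactly with its sidecar", {
  img <- phase_image(as_float32(matrix(rnorm(32 * 48, sd = 3), 32, 48)),
                     pixel_size = 0.1, wavelength = 552)
  path <- tempfile(fileext = ".tif")
  write_phase_tiff(img, path)
  back <- read_phase_tiff(path)
  expect_identical(back$values, img$values)
  expect_identical(back$pixel_size, 0.1)
  expect_identical(back$wavelength, 552)
})

test_that("missing sidecar and integer TIFFs are rejected with clear errors", {
  img <- phase_image(matrix(0.5, 16, 16), 0.1)
  path <- tempfile(fileext = ".tif")
  write_phase_tiff(img, path)
  file.remove(sub("\\.tif$", ".json", path))
  expect_error(read_phase_tiff(path), "pixel_size_um, wavelength_nm")

  # an 8-bit integer TIFF is not a phase map
  skip_if_not_installed("tiff")
  ipath <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(64), 8, 8), ipath, compression = "none")
  jsonlite::write_json(list(pixel_size_um = 0.1, wavelength_nm = 552),
                       sub("\\.tif$", ".json", ipath), auto_unbox = TRUE)
  expect_error(read_phase_tiff(ipath), "float")
})

test_that("NaN pixels survive I/O but are rejected at measurement", {
  vals <- as_float32(matrix(rnorm(300 * 300), 300, 300))
  vals[5, 7] <- NaN
  img <- phase_image(vals, 0.1)
  path <- tempfile(fileext = ".tif")
  write_phase_tiff(img, path)
  back <- read_phase_tiff(path)
  expect_true(is.nan(back$values[5, 7]))
  expect_error(phase_variance(back, min_pixels = 1), "non-finite")
})

test_that("our float TIFFs agree with an independent reader/writer", {
  python <- Sys.which("python")
  skip_if(python == "", "python not on PATH")
  img <- phase_image(as_float32(matrix(rnorm(20 * 30, sd = 2), 20, 30)), 0.1)
  ours <- tempfile(fileext = ".tif")
  theirs <- tempfile(fileext = ".tif")
  csv_out <- tempfile(fileext = ".csv")
  write_phase_tiff(img, ours)
  script <- sprintf(paste(
    "import tifffile, numpy as np",
    "a = tifffile.imread(%s)",
    "np.savetxt(%s, a.astype(np.float64), delimiter=',')",
    "tifffile.imwrite(%s, a)",
    sep = "; "
  ), shQuote(ours), shQuote(csv_out), shQuote(theirs))
  status <- system2(python, c("-c", shQuote(script)))
  skip_if(status != 0, "python tifffile unavailable")
  ref <- as.matrix(utils::read.csv(csv_out, header = FALSE))
  dimnames(ref) <- NULL
  expect_equal(ref, img$values, tolerance = 1e-7)
  file.copy(sub("\\.tif$", ".json", ours), sub("\\.tif$", ".json", theirs))
  expect_identical(read_phase_tiff(theirs)$values, img$values)
})

test_that("ROI JSON round-trips vertices and identifiers exactly", {
  r1 <- roi_polygon(cbind(c(0.25, 10, 5.5), c(0, 0.125, 9)),
                    label = "stroma_1", core_id = "C1", patient_id = "P1")
  r2 <- annulus_roi(c(50, 40), 10, 20, label = "ring")
  path <- tempfile(fileext = ".json")
  write_roi_json(list(r1, r2), path)
  back <- read_roi_json(path)
  expect_length(back, 2)
  expect_identical(back[[1]]$vertices, r1$vertices)
  expect_identical(back[[1]]$label, "stroma_1")
  expect_identical(back[[1]]$patient_id, "P1")
  expect_identical(back[[2]]$vertices, r2$vertices)
})

test_that("ImageJ .roi files round-trip integer polygons", {
  v <- cbind(c(12, 40, 35, 10), c(8, 10, 30, 28))
  roi <- roi_polygon(v, label = "gland")
  path <- tempfile(fileext = ".roi")
  write_imagej_roi(roi, path)
  back <- read_imagej_roi(path)
  expect_equal(unname(back$vertices), unname(v))
  # zip archives of .roi files (archive built with python's zipfile)
  python <- Sys.which("python")
  skip_if(python == "", "python not on PATH")
  zipdir <- tempfile(); dir.create(zipdir)
  write_imagej_roi(roi, file.path(zipdir, "a.roi"))
  write_imagej_roi(roi_polygon(v + 5), file.path(zipdir, "b.roi"))
  zipfile <- tempfile(fileext = ".zip")
  script <- sprintf(
    "import zipfile, os; z = zipfile.ZipFile(%s, 'w'); [z.write(os.path.join(%s, f), f) for f in ['a.roi', 'b.roi']]; z.close()",
    shQuote(zipfile), shQuote(zipdir)
  )
  status <- system2(python, c("-c", shQuote(script)))
  skip_if(status != 0, "python unavailable")
  rois <- read_imagej_roi_zip(zipfile)
  expect_length(rois, 2)
  expect_equal(unname(rois[[1]]$vertices), unname(v))
})

test_that("roi_polygon validates geometry", {
  expect_error(roi_polygon(cbind(c(0, 1), c(0, 1))), ">= 3 rows")
  expect_error(roi_polygon(cbind(c(0, 1, 2), c(0, 0, 0))), "zero area")
  crossed <- cbind(c(0, 10, 0, 9), c(0, 8, 10, 1))
  expect_error(roi_polygon(crossed), "self-intersecting")
})

test_that("rasterization matches pixel-center counts on squares and annuli", {
  sq <- roi_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  mask <- rasterize_roi(sq, c(20, 20))
  expect_equal(sum(mask), 100)

  outside <- roi_polygon(cbind(c(30, 40, 40, 30), c(30, 30, 40, 40)))
  # clipped to the image bounds and empty: both conditions are reported
  expect_warning(expect_warning(m2 <- rasterize_roi(outside, c(20, 20)),
                                "beyond"), "empty")
  expect_equal(sum(m2), 0)

  # annulus: even-odd keyhole polygon equals brute force and the
  # analytic outer-minus-inner area
  ring <- annulus_roi(c(12, 12), 4, 9)
  m3 <- rasterize_roi(ring, c(25, 25))
  expect_identical(m3, bf_rasterize(ring$vertices, c(25, 25)))
  expect_lt(abs(sum(m3) - pi * (9^2 - 4^2)), 8)
})

test_that("rasterization agrees with brute-force point-in-polygon", {
  set.seed(404)
  for (i in 1:200) {
    n <- sample(3:6, 1)
    v <- cbind(runif(n, 0, 20), runif(n, 0, 20))
    roi <- try(roi_polygon(v, check_simple = FALSE), silent = TRUE)
    if (inherits(roi, "try-error")) next
    expect_identical(suppressWarnings(rasterize_roi(roi, c(20, 20))),
                     bf_rasterize(v, c(20, 20)))
  }
})

test_that("mask area tracks the analytic area of convex polygons", {
  set.seed(11)
  for (i in 1:20) {
    cx <- runif(1, 30, 70); cy <- runif(1, 30, 70); rad <- runif(1, 8, 25)
    th <- sort(runif(8, 0, 2 * pi))
    v <- cbind(cx + rad * cos(th), cy + rad * sin(th))
    roi <- roi_polygon(v, check_simple = FALSE)
    mask <- rasterize_roi(roi, c(100, 100))
    # within one pixel-row of the shoelace area
    expect_lt(abs(sum(mask) - abs(polygon_area(v))), 2 * rad + 2)
  }
})
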