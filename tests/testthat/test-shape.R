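test_that("orientation follows the principal axis with the documented tie-break", {
  horiz <- ellipseBoundary(a = 12, b = 5, phi = 0)
  expect_lt(min(glandOrientation(horiz), 180 - glandOrientation(horiz)), 1)
  rot30 <- ellipseBoundary(a = 12, b = 5, phi = 30 * pi / 180)
  expect_lt(abs(glandOrientation(rot30) - 30), 1)
  # circle: principal axes tied -> documented lower-angle result 0
  expect_identical(glandOrientation(circleBoundary(r = 8)), 0)
  # collinear boundary errors
  line <- cbind(1:10, 2 * (1:10))
  expect_error(glandOrientation(line), "collinear")
})

test_that("orientation angles land in the documented 10-degree bins", {
  expect_identical(glandstab:::orientationBin(95), 10L)   # 1-based bin 10
  expect_identical(glandstab:::orientationBin(0), 1L)
  expect_identical(glandstab:::orientationBin(179.9), 18L)
})

test_that("shape features have length 100 and are translation invariant", {
  sim <- smallRoi()
  f1 <- shapeFeatures(sim$glands)
  expect_length(f1, 100L)
  moved <- GlandSet(lapply(sim$glands@boundaries, function(b)
    sweep(b, 2, c(-17.5, 31.2), "+")), mpp = sim$glands@mpp)
  f2 <- shapeFeatures(moved)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("identical glands force the degenerate aggregates", {
  b <- circleBoundary(r = 9)
  gs <- GlandSet(list(b, sweep(b, 2, c(60, 0), "+"),
                      sweep(b, 2, c(0, 60), "+")), mpp = 4)
  f <- shapeFeatures(gs)
  expect_equal(unname(f["shape_std_smoothness"]), 0)
  expect_equal(unname(f["shape_minmax_invariant_moment_1"]), 1)
  expect_equal(unname(f["shape_std_area"]), 0)
})

test_that("Hu moments and Fourier magnitudes are rotation invariant", {
  b <- ellipseBoundary(a = 14, b = 6, phi = 0.3, n = 96)
  # a second, asymmetric shape: perturbed ellipse
  set.seed(7)
  radii <- 10 + 2 * sin(3 * seq(0, 2 * pi, length.out = 97)[-97]) +
    rnorm(96, 0, 0.2)
  t <- seq(0, 2 * pi, length.out = 97)[-97]
  b2 <- cbind(radii * cos(t), radii * sin(t))
  sm <- glandstab:::shapeMeasurements
  for (shape in list(b, b2)) {
    base <- sm(GlandSet(list(shape), mpp = 16))[1, ]
    for (deg in c(37, 118)) {
      rot <- sm(GlandSet(list(
        sweep(rotateBoundary(shape, deg), 2, c(5, -3), "+")), mpp = 16))[1, ]
      hu <- paste0("invariant_moment_", 1:7)
      fd <- paste0("fourier_descriptor_", 1:9)
      expect_equal(rot[hu], base[hu], tolerance = 1e-6)
      expect_equal(rot[fd], base[fd], tolerance = 1e-6)
    }
  }
})

test_that("single-gland ROIs give std 0 and min/max ratio 1", {
  gs <- GlandSet(list(ellipseBoundary(a = 10, b = 7)), mpp = 4)
  f <- shapeFeatures(gs)
  stds <- f[grepl("^shape_std_", names(f))]
  mm <- f[grepl("^shape_minmax_", names(f))]
  expect_true(all(stds == 0))
  expect_true(all(mm == 1))
})

test_that("shape measurements behave sensibly on a circle", {
  # a circle of radius 10 at the 16 um/px feature scale
  m <- glandstab:::shapeMeasurements(
    GlandSet(list(circleBoundary(r = 10, n = 128)), mpp = 16))[1, ]
  expect_lt(abs(m["area"] - pi * 100) / (pi * 100), 0.01)
  expect_lt(abs(m["perimeter"] - 2 * pi * 10) / (2 * pi * 10), 0.01)
  expect_gt(m["area_ratio"], 0.97)        # circle fills its enclosing circle
  expect_gt(m["perimeter_ratio"], 0.99)   # convex shape
  expect_equal(unname(m["distance_ratio"]), 1, tolerance = 1e-9)
  expect_lt(abs(m["fractal_dimension"] - 1), 0.25)  # smooth curve
  expect_lt(abs(m["invariant_moment_1"] - 1 / (2 * pi)), 1e-3)
})
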