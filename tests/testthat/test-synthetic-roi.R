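test_that("ROI generation is a pure function of spec and seed", {
  a <- simulateRoi("noncancer", imageSize = c(192L, 192L), nGlands = 8L,
                   seed = 1L)
  b <- simulateRoi("noncancer", imageSize = c(192L, 192L), nGlands = 8L,
                   seed = 1L)
  expect_identical(imagePixels(a$roi), imagePixels(b$roi))
  expect_identical(a$glands@boundaries, b$glands@boundaries)
  c <- simulateRoi("noncancer", imageSize = c(192L, 192L), nGlands = 8L,
                   seed = 2L)
  expect_false(identical(imagePixels(a$roi), imagePixels(c$roi)))
})

test_that("ground truth matches the requested construction", {
  sim <- simulateRoi("noncancer", imageSize = c(192L, 192L), nGlands = 3L,
                     lumenFraction = 1, seed = 3L)
  expect_equal(glandCount(sim$glands), 3L)
  h <- dim(imagePixels(sim$roi))[1]; w <- dim(imagePixels(sim$roi))[2]
  for (i in 1:3) {
    poly <- sim$glands@boundaries[[i]]
    expect_true(glandstab:::pointInPolygon(sim$glands@centroids[i, ], poly))
    expect_true(all(poly[, 1] >= 0 & poly[, 1] <= w - 1))
    expect_true(all(poly[, 2] >= 0 & poly[, 2] <= h - 1))
  }
  expect_true(all(sim$glands@lumenAreas > 0))
})

test_that("crowding packs centroids closer (same seed, direct distances)", {
  benign <- simulateRoi("noncancer", imageSize = c(384L, 384L), nGlands = 35L,
                        glandRadiusMeanUm = 50, crowding = 1, seed = 5L)
  crowded <- simulateRoi("cancer", imageSize = c(384L, 384L), nGlands = 35L,
                         glandRadiusMeanUm = 50, crowding = 2, seed = 5L)
  nnDist <- function(gs) {
    D <- as.matrix(dist(centroids(gs)))
    diag(D) <- Inf
    mean(apply(D, 1, min))
  }
  expect_lt(nnDist(crowded$glands), nnDist(benign$glands))
})

test_that("infeasible placement raises a parameter-naming error", {
  expect_error(
    simulateRoi("noncancer", imageSize = c(96L, 96L), nGlands = 200L,
                glandRadiusMeanUm = 60, crowding = 0.5, seed = 1L),
    "infeasible")
})

test_that("identity site effect is bit-identical", {
  sim <- smallRoi()
  out <- applySiteEffect(sim$roi, siteEffect("x"))
  expect_identical(imagePixels(out), imagePixels(sim$roi))
})

test_that("pure red shift moves the mean red channel by exactly the shift", {
  px <- pmin(imagePixels(smallRoi()$roi), 235)  # keep headroom for +20
  roi <- RoiImage(px, mpp = 4)
  out <- applySiteEffect(roi, siteEffect("x", rgbShift = c(20, 0, 0)))
  expect_equal(mean(imagePixels(out)[, , 1]) - mean(px[, , 1]), 20)
  expect_equal(imagePixels(out)[, , 2], px[, , 2])
})

test_that("two distinct site effects separate a mean-intensity feature", {
  sim <- simulateRoi("noncancer", imageSize = c(128L, 128L), nGlands = 4L,
                     seed = 11L)
  effA <- siteEffect("a", rgbShift = c(8, 8, 8), blurSigmaPx = 0.5)
  effB <- siteEffect("b", rgbShift = c(-8, -8, -8), stainRotationDeg = 5)
  # per-copy noise comes from re-rendering with a fresh seed, then the two
  # effects are applied to each copy
  meanInt <- function(eff, s) {
    r <- simulateRoi("noncancer", imageSize = c(128L, 128L), nGlands = 4L,
                     seed = s)$roi
    mean(imagePixels(applySiteEffect(r, eff, seed = s)))
  }
  a <- vapply(1:30, function(s) meanInt(effA, s), numeric(1))
  b <- vapply(1:30, function(s) meanInt(effB, s), numeric(1))
  expect_lt(wilcox.test(a, b)$p.value, 0.05)
})

test_that("gland dropout removes glands and requires the geometry", {
  sim <- simulateRoi("noncancer", imageSize = c(256L, 256L), nGlands = 15L,
                     seed = 7L)
  expect_error(applySiteEffect(sim$roi,
                               siteEffect("x", glandDropoutRate = 0.5)),
               "glands")
  dd <- dropGlands(sim$roi, sim$glands, rate = 0.5, seed = 9L)
  expect_lt(glandCount(dd$glands), 15L)
  expect_false(identical(imagePixels(dd$roi), imagePixels(sim$roi)))
})
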