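test_that("an all-white image has no tissue above the OD threshold", {
  px <- array(250, c(64, 64, 3))
  expect_error(estimateStainModel(RoiImage(px, mpp = 4)),
               "insufficient tissue")
})

test_that("stain vectors are recovered from a two-stain forward model", {
  # build an image from two known OD stain vectors at mixed concentrations
  h <- c(0.65, 0.70, 0.29); h <- h / sqrt(sum(h^2))
  e <- c(0.09, 0.95, 0.28); e <- e / sqrt(sum(e^2))
  withr::with_seed(21, {
    cH <- runif(4096, 0.05, 1.2)
    cE <- runif(4096, 0.05, 1.0)
    # include near-pure pixels of each stain so the percentile angles of the
    # mixture reach the true stain directions
    pureH <- sample(4096, 400); pureE <- setdiff(sample(4096, 800), pureH)[1:400]
    cE[pureH] <- 0.005
    cH[pureE] <- 0.005
  })
  od <- cbind(cH, cE) %*% rbind(h, e)
  px <- array(0, c(64, 64, 3))
  for (ch in 1:3) px[, , ch] <- matrix(pmax(0, 256 * 10^(-od[, ch]) - 1), 64)
  model <- estimateStainModel(RoiImage(px, mpp = 4))
  angdeg <- function(u, v) acos(pmin(1, abs(sum(u * v)))) * 180 / pi
  expect_lt(angdeg(model@vectors[, 1], h), 2)
  expect_lt(angdeg(model@vectors[, 2], e), 2)
})

test_that("degenerate percentile configuration is rejected", {
  sim <- smallRoi()
  expect_error(estimateStainModel(sim$roi, anglePercentiles = c(50, 50)),
               "collinear")
})

test_that("self-normalization reproduces the per-stain histograms", {
  sim <- smallRoi()
  tm <- estimateStainModel(sim$roi)
  out <- normalizeImage(sim$roi, tm, tm)
  m2 <- estimateStainModel(out)
  for (s in 1:2) {
    q1 <- tm@refQuantiles[[s]]
    q2 <- m2@refQuantiles[[s]]
    expect_lt(mean(abs(q1 - q2)), 0.05 * max(q1))  # up to discretization
  }
})

test_that("normalization to a common template brings site copies closer", {
  sim <- smallRoi()
  a <- applySiteEffect(sim$roi, siteEffect("a", rgbShift = c(12, -6, 4),
                                           stainRotationDeg = 7))
  b <- applySiteEffect(sim$roi, siteEffect("b", rgbShift = c(-10, 8, -6),
                                           contrastScale = 1.1))
  tm <- estimateStainModel(sim$roi)
  na <- normalizeImage(a, estimateStainModel(a), tm)
  nb <- normalizeImage(b, estimateStainModel(b), tm)
  dBefore <- mean(abs(imagePixels(a) - imagePixels(b)))
  dAfter <- mean(abs(imagePixels(na) - imagePixels(nb)))
  expect_lt(dAfter, dBefore)
})

test_that("background pixels pass through and output stays 8-bit valid", {
  sim <- smallRoi()
  px <- imagePixels(sim$roi)
  px[1:10, 1:10, ] <- 252  # near-white background block (OD below threshold)
  roi <- RoiImage(px, mpp = 4)
  tm <- estimateStainModel(roi)
  m <- estimateStainModel(applySiteEffect(roi, siteEffect("x",
                                                          rgbShift = c(5, 0, 0))))
  out <- normalizeImage(roi, m, tm)
  pxo <- imagePixels(out)
  expect_true(all(pxo >= 0 & pxo <= 255))
  expect_true(all(abs(pxo[1:10, 1:10, ] - 252) <= 10))
})

test_that("normalization is approximately idempotent", {
  sim <- smallRoi()
  shifted <- applySiteEffect(sim$roi, siteEffect("a", rgbShift = c(10, -5, 3)))
  tm <- estimateStainModel(sim$roi)
  once <- normalizeImage(shifted, estimateStainModel(shifted), tm)
  twice <- normalizeImage(once, estimateStainModel(once), tm)
  for (ch in 1:3)
    expect_lt(abs(mean(imagePixels(twice)[, , ch]) -
                    mean(imagePixels(once)[, , ch])), 2)
})

test_that("stain models round-trip through the text schema", {
  sim <- smallRoi()
  tm <- estimateStainModel(sim$roi)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeStainModel(tm, path)
  back <- readStainModel(path)
  expect_equal(back@vectors, tm@vectors, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back@refQuantiles[[1]], tm@refQuantiles[[1]], tolerance = 1e-6)
})
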