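test_that("empirical AUC matches the trivial and brute-force cases", {
  expect_equal(empiricalAuc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(empiricalAuc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  expect_error(empiricalAuc(1:4, c(1, 1, 1, 1)), "both classes")
  withr::with_seed(31, {
    v <- rnorm(20); y <- rbinom(20, 1, 0.5)
  })
  y[1] <- 0; y[2] <- 1  # guarantee both classes
  # O(n^2) pair-counting oracle with half credit for ties
  pos <- v[y == 1]; neg <- v[y == 0]
  oracle <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(empiricalAuc(v, y), oracle)
})

test_that("the stability gate keeps exactly the strict survivors", {
  prof <- new("InstabilityProfile",
              pi = c(a = 0, b = 1 / 3, c = 2 / 3, d = 1, e = 0),
              protocol = list(mode = "exact", alpha = 0.05),
              sites = c("s1", "s2", "s3"))
  expect_identical(stabilityGate(letters[1:5], prof, 0.25), c("a", "e"))
  expect_identical(stabilityGate(letters[1:5], prof, 1.01), letters[1:5])
  # monotone in the threshold
  t1 <- stabilityGate(letters[1:5], prof, 0.4)
  t2 <- stabilityGate(letters[1:5], prof, 0.7)
  expect_true(all(t1 %in% t2))
  expect_error(stabilityGate(letters[1:4], prof, 0), "no features pass")
  expect_error(stabilityGate(c("a", "zz"), prof, 0.5), "zz")
})

test_that("all four selectors rank a planted 3-sigma feature first", {
  ft <- simulateFeatureTable(nSites = 2, nRegionsPerSite = 60,
                             nFeatures = 21,
                             discriminative = setNames(3, "7"), seed = 41)
  lab <- glandstab:::taskLabels(ft, "cancer")
  for (th in c("ROC", "WLCX", "mRMR", "SFS")) {
    sel <- selectFeatures(ft, lab, theta = th, k = 3, seed = 2)
    expect_identical(selectedFeatures(sel)[1], "f007")
  }
})

test_that("ROC k=1 equals the standalone arg-max and SFS k=1 the CV arg-max", {
  ft <- simulateFeatureTable(nSites = 2, nRegionsPerSite = 30, nFeatures = 8,
                             discriminative = setNames(c(1.5, 0.8),
                                                       c("2", "5")),
                             seed = 43)
  lab <- glandstab:::taskLabels(ft, "cancer")
  X <- t(featureValues(ft))
  aucs <- apply(X, 2, function(v) {
    a <- empiricalAuc(v, lab); max(a, 1 - a)
  })
  sel <- selectFeatures(ft, lab, theta = "ROC", k = 1)
  expect_identical(selectedFeatures(sel), names(which.max(aucs)))
  # SFS k=1: exhaustive loop over single-feature seeded CV objectives
  y <- glandstab:::asBinary(lab)
  foldMat <- glandstab:::makeFoldMatrix(y, 10L, 3L, seed = 5L)
  objs <- vapply(seq_len(ncol(X)), function(j)
    glandstab:::cvAucFast(X[, j, drop = FALSE], y, foldMat, "QDA"),
    numeric(1))
  sfs1 <- selectFeatures(ft, lab, theta = "SFS", k = 1, seed = 5L)
  expect_identical(selectedFeatures(sfs1), colnames(X)[which.max(objs)])
})

test_that("selectors are deterministic and tolerate constant features", {
  ft <- simulateFeatureTable(nSites = 2, nRegionsPerSite = 20, nFeatures = 7,
                             seed = 47)
  vals <- featureValues(ft); vals[3, ] <- 1.5
  ft2 <- FeatureTable(vals, regionInfo(ft))
  lab <- glandstab:::taskLabels(ft2, "cancer")
  for (th in c("ROC", "WLCX", "mRMR", "SFS")) {
    s1 <- selectFeatures(ft2, lab, theta = th, k = 5, seed = 9)
    s2 <- selectFeatures(ft2, lab, theta = th, k = 5, seed = 9)
    expect_identical(selectedFeatures(s1), selectedFeatures(s2))
    expect_length(selectedFeatures(s1), 5L)
  }
})

test_that("gated selection output is a subset of the gate survivors", {
  ft <- confoundedTable(seed = 51)
  lab <- glandstab:::taskLabels(ft, "cancer")
  prof <- preparationInstability(ft, restrictClass = "noncancer")
  surv <- stabilityGate(rownames(ft), prof, 0.25)
  sel <- selectFeatures(ft, lab, theta = "WLCX", k = 5, candidates = surv,
                        gated = TRUE, piThreshold = 0.25)
  expect_true(all(selectedFeatures(sel) %in% surv))
  expect_false(any(S4Vectors::metadata(ft)$unstable %in%
                     selectedFeatures(sel)))
})
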