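test_that("table generation is deterministic and carries ground truth", {
  a <- simulateFeatureTable(nSites = 3, nRegionsPerSite = 10, nFeatures = 8,
                            unstable = setNames(2, "4"), seed = 5)
  b <- simulateFeatureTable(nSites = 3, nRegionsPerSite = 10, nFeatures = 8,
                            unstable = setNames(2, "4"), seed = 5)
  expect_identical(featureValues(a), featureValues(b))
  expect_identical(S4Vectors::metadata(a)$unstable, "f004")
  info <- regionInfo(a)
  expect_identical(colnames(featureValues(a)), info$region_id)
  expect_setequal(unique(info$site), c("site01", "site02", "site03"))
})

test_that("invalid feature indices are rejected", {
  expect_error(simulateFeatureTable(nFeatures = 5,
                                    discriminative = setNames(1, "9"),
                                    seed = 1),
               "invalid discriminative")
  expect_error(simulateFeatureTable(nFeatures = 5,
                                    unstable = setNames(1, "0"), seed = 1),
               "invalid unstable")
})

test_that("null tables give near-zero exact-mode PI (type-I behaviour)", {
  ft <- simulateFeatureTable(nSites = 3, nRegionsPerSite = 40,
                             nFeatures = 60, seed = 17)
  prof <- preparationInstability(ft, alpha = 0.05, restrictClass = NULL)
  # with 3 i.i.d. sites, a feature has PI = 0 unless one of its 3 pairwise
  # tests rejects; P(PI = 0) >= 1 - 3 * alpha = 0.85, so >= 90% of features
  # at PI = 0 is comfortably within binomial noise for alpha = 0.05 tests
  expect_gte(mean(piValues(prof) == 0), 0.80)
  expect_lte(mean(piValues(prof)), 0.05 + 3 * sqrt(0.05 * 0.95 / 180))
})

test_that("a 3-sigma site shift in one of three sites yields exact PI 2/3", {
  sh <- matrix(0, 1, 3, dimnames = list("2", NULL))
  sh[1, 3] <- 3
  ft <- simulateFeatureTable(nSites = 3, nRegionsPerSite = 40, nFeatures = 5,
                             siteShifts = sh, seed = 23)
  prof <- preparationInstability(ft, restrictClass = NULL)
  expect_equal(unname(piValues(prof)["f002"]), 2 / 3)
})

test_that("a 2-sigma class effect gives pooled empirical AUC near 0.92", {
  # closed form: AUC of two unit-variance Gaussians 2 sigma apart is
  # pnorm(2 / sqrt(2)) = 0.9214
  ft <- simulateFeatureTable(nSites = 3, nRegionsPerSite = 80, nFeatures = 5,
                             discriminative = setNames(2, "1"), seed = 31)
  lab <- glandstab:::taskLabels(ft, "cancer")
  auc <- empiricalAuc(featureValues(ft)["f001", ], lab)
  expect_gt(auc, 0.85)
  expect_lt(abs(auc - pnorm(sqrt(2))), 0.06)
})

test_that("site-shift magnitude monotonically increases expected PI", {
  piAt <- function(shift) {
    mean(vapply(1:5, function(r) {
      sh <- matrix(0, 1, 3, dimnames = list("1", NULL)); sh[1, 2] <- shift
      ft <- simulateFeatureTable(nSites = 3, nRegionsPerSite = 15,
                                 nFeatures = 1, siteShifts = sh,
                                 seed = 100 + r)
      unname(piValues(preparationInstability(ft, restrictClass = NULL)))
    }, numeric(1)))
  }
  pis <- c(piAt(0), piAt(0.8), piAt(3))
  expect_true(all(diff(pis) >= 0))
  expect_lt(pis[1], 0.2)
  expect_equal(pis[3], 2 / 3)
})

test_that("lognormal noise family produces positive values", {
  ft <- simulateFeatureTable(nSites = 2, nRegionsPerSite = 6, nFeatures = 4,
                             noiseFamily = "lognormal", seed = 2)
  expect_true(all(featureValues(ft) > 0))
})
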