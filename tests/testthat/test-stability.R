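makeSiteTable <- function(nSites, nRegions, nFeatures, seed,
                          siteShifts = NULL) {
  simulateFeatureTable(nSites = nSites, nRegionsPerSite = nRegions,
                       nFeatures = nFeatures, siteShifts = siteShifts,
                       seed = seed)
}

test_that("identical feature values across sites give PI exactly 0", {
  ft <- makeSiteTable(3, 10, 4, seed = 1)
  vals <- featureValues(ft)
  vals[1, ] <- 7.5  # constant feature
  ft2 <- FeatureTable(vals, regionInfo(ft))
  prof <- suppressWarnings(
    preparationInstability(ft2, restrictClass = NULL))
  expect_equal(unname(piValues(prof)["f001"]), 0)
})

test_that("a 10-sigma shifted site rejects exactly its two pairs", {
  sh <- matrix(0, 1, 3, dimnames = list("1", NULL)); sh[1, 2] <- 10
  ft <- makeSiteTable(3, 12, 3, seed = 2, siteShifts = sh)
  prof <- preparationInstability(ft, restrictClass = NULL)
  expect_equal(unname(piValues(prof)["f001"]), 2 / 3)
})

test_that("exact-mode PI over 4 sites lives on the 1/6 grid", {
  sh <- matrix(0, 2, 4, dimnames = list(c("1", "2"), NULL))
  sh[1, 2] <- 5; sh[2, c(2, 4)] <- 5
  ft <- makeSiteTable(4, 10, 6, seed = 3, siteShifts = sh)
  prof <- preparationInstability(ft, restrictClass = NULL)
  expect_true(all(abs(piValues(prof) * 6 - round(piValues(prof) * 6)) < 1e-9))
})

test_that("exact-mode PI equals the brute-force site-pair loop", {
  sh <- matrix(0, 3, 4, dimnames = list(c("1", "3", "5"), NULL))
  sh[1, 4] <- 3; sh[2, c(1, 2)] <- 2; sh[3, 1] <- 0.5
  ft <- makeSiteTable(4, 10, 8, seed = 4, siteShifts = sh)
  prof <- preparationInstability(ft, alpha = 0.05, restrictClass = NULL)
  # independently coded oracle
  vals <- featureValues(ft)
  site <- regionInfo(ft)$site
  us <- sort(unique(site))
  oracle <- vapply(rownames(vals), function(f) {
    rej <- 0; tot <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      p <- suppressWarnings(wilcox.test(vals[f, site == us[i]],
                                        vals[f, site == us[j]]))$p.value
      rej <- rej + (p < 0.05); tot <- tot + 1
    }
    rej / tot
  }, numeric(1))
  expect_equal(piValues(prof), oracle)
})

test_that("PI is invariant under strictly monotone feature transforms", {
  sh <- matrix(0, 1, 3, dimnames = list("2", NULL)); sh[1, 1] <- 1.5
  ft <- makeSiteTable(3, 15, 4, seed = 5, siteShifts = sh)
  vals <- featureValues(ft)
  trans <- exp(vals / 2) + 3
  ft2 <- FeatureTable(trans, regionInfo(ft))
  p1 <- preparationInstability(ft, restrictClass = NULL)
  p2 <- preparationInstability(ft2, restrictClass = NULL)
  expect_identical(piValues(p1), piValues(p2))
})

test_that("sites below four regions are reported by name", {
  ft <- makeSiteTable(3, 10, 3, seed = 6)
  ft2 <- ft[, c(1:10, 11:13, 21:30)]  # site02 left with 3 regions
  expect_error(preparationInstability(ft2, restrictClass = NULL), "site02")
})

test_that("subsampled-mode PI approaches exact-mode PI at full size", {
  sh <- matrix(0, 1, 3, dimnames = list("1", NULL)); sh[1, 3] <- 2.5
  ft <- makeSiteTable(3, 16, 3, seed = 7, siteShifts = sh)
  exact <- preparationInstability(ft, restrictClass = NULL)
  subs <- preparationInstability(ft, mode = "subsampled", repetitions = 30,
                                 subsampleSize = 16, seed = 11,
                                 restrictClass = NULL)
  expect_equal(piValues(subs), piValues(exact))  # full-size subsample
  half <- preparationInstability(ft, mode = "subsampled", repetitions = 50,
                                 subsampleSize = 8, seed = 11,
                                 restrictClass = NULL)
  expect_true(all(abs(piValues(half) - piValues(exact)) <= 0.5))
  expect_lt(mean(abs(piValues(half) - piValues(exact))), 0.25)
})

test_that("LI is calibrated at alpha for i.i.d. features and 0 for constants", {
  ft <- makeSiteTable(1, 40, 30, seed = 8)
  li <- latentInstability(ft, repetitions = 60, seed = 9)
  # mean LI over 30 i.i.d. features ~ alpha within 3 binomial SEs of the
  # feature-averaged estimate
  expect_lt(abs(mean(li) - 0.05), 3 * sqrt(0.05 * 0.95 / (30 * 60)) + 0.02)
  vals <- featureValues(ft); vals[1, ] <- 2
  ft2 <- FeatureTable(vals, regionInfo(ft))
  li2 <- suppressWarnings(latentInstability(ft2, repetitions = 20, seed = 10))
  expect_equal(unname(li2["f001"]), 0)
  # determinism
  expect_identical(li, latentInstability(ft, repetitions = 60, seed = 9))
  expect_error(latentInstability(ft[, 1:6], repetitions = 5, seed = 1),
               "at least 8")
})

test_that("the PI-AUC map is consistent with its standalone components", {
  ft <- simulateFeatureTable(nSites = 3, nRegionsPerSite = 20, nFeatures = 6,
                             discriminative = setNames(3, "2"), seed = 12)
  map <- piAucMap(ft, task = "cancer", cvIterations = 5, seed = 13)
  expect_equal(nrow(map), 6L)
  prof <- preparationInstability(ft, restrictClass = "noncancer", seed = 13)
  expect_equal(map$pi, unname(piValues(prof)[map$feature]))
  expect_gt(map$mean_auc[map$feature == "f002"], 0.9)
  noise <- setdiff(map$feature, "f002")
  expect_true(all(abs(map$mean_auc[map$feature %in% noise] - 0.5) < 0.2))
})

test_that("single-class sites are rejected by the PI-AUC map", {
  ft <- simulateFeatureTable(nSites = 3, nRegionsPerSite = 10, nFeatures = 3,
                             seed = 14)
  info <- regionInfo(ft)
  info$class[info$site == "site01"] <- "cancer"
  ft2 <- FeatureTable(featureValues(ft), info)
  expect_error(piAucMap(ft2, task = "cancer", cvIterations = 2),
               "site01")
})
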