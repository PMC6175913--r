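test_that("classifier wrappers separate separable data and stay calibrated", {
  withr::with_seed(61, {
    X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 4), 100, 2))
    y <- rep(c(0, 1), each = 100)
    ord <- sample(200)
  })
  X <- X[ord, ]; y <- y[ord]
  tr <- 1:120; te <- 121:200
  for (ka in c("LDA", "QDA", "SVM", "RF")) {
    sc <- fitPredictScores(X[tr, ], y[tr], X[te, ], kappa = ka, seed = 1)
    expect_gt(empiricalAuc(sc, y[te]), 0.99)
  }
  # permuted labels give chance-level AUC
  withr::with_seed(62, yperm <- sample(y))
  for (ka in c("LDA", "RF")) {
    sc <- fitPredictScores(X[tr, ], yperm[tr], X[te, ], kappa = ka, seed = 2)
    expect_lt(abs(empiricalAuc(sc, yperm[te]) - 0.5), 0.12)
  }
  # RF determinism under a fixed seed
  s1 <- fitPredictScores(X[tr, ], y[tr], X[te, ], kappa = "RF", seed = 3)
  s2 <- fitPredictScores(X[tr, ], y[tr], X[te, ], kappa = "RF", seed = 3)
  expect_identical(s1, s2)
  expect_error(fitPredictScores(X[tr, ], y[tr], X[te, ], kappa = "XX"),
               "unknown classifier")
})

test_that("LDA/QDA agree with the MASS reference on well-posed data", {
  withr::with_seed(63, {
    X <- rbind(matrix(rnorm(120, 0), 60, 2),
               matrix(rnorm(120, 1.2), 60, 2))
    y <- rep(c(0, 1), each = 60)
    Xt <- matrix(rnorm(80), 40, 2)
  })
  for (ka in c("LDA", "QDA")) {
    sc <- fitPredictScores(X, y, Xt, kappa = ka, seed = 1)
    ref <- if (ka == "LDA") MASS::lda(X, grouping = factor(y))
           else MASS::qda(X, grouping = factor(y))
    post <- predict(ref, Xt)$posterior[, "1"]
    # identical ranking of test points
    expect_equal(order(sc), order(post))
  }
})

test_that("degenerate covariances fall back to a ridge fit instead of crashing", {
  X <- cbind(rep(c(1, 2), 10), rep(c(1, 2), 10))  # perfectly collinear
  y <- rep(c(0, 1), 10)
  sc <- fitPredictScores(X, y, X, kappa = "QDA", seed = 1)
  expect_true(all(is.finite(sc)))
})

test_that("hold-one-site-out produces one leakage-free fold per site", {
  ft <- confoundedTable(seed = 71)
  rep <- holdOneSiteOut(ft, task = "cancer", theta = "ROC", kappa = "LDA",
                        gated = TRUE, seed = 4)
  recs <- reportRecords(rep)
  expect_equal(nrow(recs), 4L)
  expect_setequal(recs$site_heldout, unique(regionInfo(ft)$site))
  # leakage contract: permuting held-out rows changes no selected set
  vals <- featureValues(ft)
  info <- regionInfo(ft)
  hold <- "site02"
  idx <- which(info$site == hold)
  withr::with_seed(5, {
    vals[, idx] <- vals[, sample(idx)]
  })
  ft2 <- FeatureTable(vals, info)
  rep2 <- holdOneSiteOut(ft2, task = "cancer", theta = "ROC", kappa = "LDA",
                         gated = TRUE, seed = 4)
  r1 <- reportRecords(rep)
  r2 <- reportRecords(rep2)
  expect_identical(r1$features[r1$site_heldout == hold],
                   r2$features[r2$site_heldout == hold])
  # folds not involving the mutated site as training data change nothing
  expect_identical(r1[r1$site_heldout == hold, "features"],
                   r2[r2$site_heldout == hold, "features"])
})

test_that("with the gate disabled by threshold >= 1, FS_sd equals FS_d", {
  ft <- confoundedTable(seed = 73)
  a <- holdOneSiteOut(ft, theta = "WLCX", kappa = "LDA", gated = TRUE,
                      piThreshold = 1.01, seed = 6)
  b <- holdOneSiteOut(ft, theta = "WLCX", kappa = "LDA", gated = FALSE,
                      seed = 6)
  expect_equal(reportRecords(a)$auc, reportRecords(b)$auc)
  expect_identical(reportRecords(a)$features, reportRecords(b)$features)
})

test_that("stability-gated selection beats ungated under site confounding", {
  # strongest class separation is site-confounded; moderate stable features
  # exist; paired over replicates the gated model should win
  wins <- vapply(1:8, function(r) {
    ft <- confoundedTable(seed = 300 + r)
    s <- mean(reportRecords(holdOneSiteOut(ft, theta = "ROC", kappa = "LDA",
                                           gated = TRUE, seed = r))$auc)
    d <- mean(reportRecords(holdOneSiteOut(ft, theta = "ROC", kappa = "LDA",
                                           gated = FALSE, seed = r))$auc)
    s > d
  }, logical(1))
  expect_gte(mean(wins), 0.75)
})

test_that("percent improvement follows its definition", {
  expect_equal(percentImprovement(0.5, 0.5), 0)
  expect_equal(percentImprovement(0.6, 0.5), 20)
  # computed from unrounded AUCs, e.g. 0.75 vs 0.67 gives 11.9
  expect_equal(round(percentImprovement(0.75, 0.67), 1), 11.9)
  expect_error(percentImprovement(0.5, 0))
})

test_that("report aggregation matches direct recomputation", {
  ft <- confoundedTable(seed = 77)
  rep <- evaluationGrid(ft, task = "cancer", thetas = "WLCX",
                        kappas = c("LDA", "RF"), seed = 7)
  summ <- summarizeReport(rep)
  recs <- reportRecords(rep)
  for (i in seq_len(nrow(summ))) {
    sel <- recs$theta == summ$theta[i] & recs$kappa == summ$kappa[i]
    expect_equal(summ$auc_sd_mean[i], mean(recs$auc[sel & recs$gated]))
    expect_equal(summ$auc_d_mean[i], mean(recs$auc[sel & !recs$gated]))
    expect_equal(summ$pct_improvement[i],
                 percentImprovement(summ$auc_sd_mean[i], summ$auc_d_mean[i]))
  }
})

test_that("normalization-effect deltas behave as constructed", {
  sh <- matrix(0, 2, 3, dimnames = list(c("1", "4"), NULL))
  sh[, 2] <- 4
  pre <- simulateFeatureTable(nSites = 3, nRegionsPerSite = 20,
                              nFeatures = 6, siteShifts = sh, seed = 81)
  # identical tables: all deltas zero
  eff0 <- normalizationEffect(pre, pre)
  expect_true(all(eff0$perFeature$delta == 0))
  # a post table with the site shift fully removed: delta = -PI_pre
  post <- simulateFeatureTable(nSites = 3, nRegionsPerSite = 20,
                               nFeatures = 6, seed = 81)
  eff <- normalizationEffect(pre, post)
  pf <- eff$perFeature
  expect_equal(pf$delta[pf$feature == "f001"],
               -pf$pi_pre[pf$feature == "f001"])
  # per-family means equal direct member averaging
  fam <- eff$perFamily
  for (i in seq_len(nrow(fam))) {
    memb <- pf$family %in% fam$family[i]
    expect_equal(fam$pi_pre[i], mean(pf$pi_pre[memb]))
  }
  expect_error(normalizationEffect(pre, post[, 1:10]), "same regions")
})
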