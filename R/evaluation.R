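# Hold-one-site-out evaluation of stability-gated (FS_sd) vs ungated (FS_d)
# feature selection. Within every fold: PI from the training sites'
# non-cancerous regions only, optional stability gate, selection on training
# rows, classifier trained on the top-k features, AUC measured on the
# held-out site. Held-out rows are never touched before scoring.

#' Hold-one-site-out evaluation
#'
#' @param table a [FeatureTable-class] with >= 3 sites; every site must
#'   contain both task classes, and non-cancerous rows in every site for the
#'   PI step.
#' @param task `"cancer"` or `"gleason"`.
#' @param theta selector id (see [selectFeatures()]).
#' @param kappa classifier id (see [fitPredictScores()]).
#' @param gated `TRUE` for stability-gated selection (FS_sd).
#' @param k number of selected features (default 5).
#' @param piThreshold stability-gate threshold (default 0.25).
#' @param alpha PI significance level.
#' @param piMode PI protocol mode.
#' @param seed integer seed.
#' @param sfsIterations SFS objective CV iterations.
#' @return An [EvaluationReport-class] with one record per held-out site.
#' @export
holdOneSiteOut <- function(table, task = c("cancer", "gleason"),
                           theta = "ROC", kappa = "LDA", gated = FALSE,
                           k = 5L, piThreshold = 0.25, alpha = 0.05,
                           piMode = "exact", seed = 1L,
                           sfsIterations = 10L) {
  task <- match.arg(task)
  info <- regionInfo(table)
  sites <- sort(unique(info$site))
  if (length(sites) < 3L) stop("hold-one-site-out needs at least 3 sites")
  lab <- taskLabels(table, task)
  for (s in sites) {
    if (length(unique(lab[info$site == s & !is.na(lab)])) < 2L)
      stop("site lacks both task classes: ", s)
    if (!any(info$class == "noncancer" & info$site == s))
      stop("site lacks non-cancerous regions for the PI step: ", s)
  }
  vals <- featureValues(table)

  recs <- list()
  for (holdout in sites) {
    trainCols <- info$site != holdout
    trainTab <- table[, trainCols]
    prof <- preparationInstability(trainTab, alpha = alpha, mode = piMode,
                                   seed = childSeed(seed, match(holdout, sites)),
                                   restrictClass = "noncancer")
    cand <- rownames(vals)
    if (gated) cand <- stabilityGate(cand, prof, threshold = piThreshold)

    trainRows <- trainCols & !is.na(lab)
    testRows <- !trainCols & !is.na(lab)
    selRes <- selectFeatures(t(vals[, trainRows, drop = FALSE]),
                             lab[trainRows], theta = theta, k = k,
                             candidates = cand,
                             seed = childSeed(seed, 17 * match(holdout, sites)),
                             sfsIterations = sfsIterations,
                             gated = gated, piThreshold = piThreshold)
    feats <- selectedFeatures(selRes)
    sc <- fitPredictScores(t(vals[feats, trainRows, drop = FALSE]),
                           lab[trainRows],
                           t(vals[feats, testRows, drop = FALSE]),
                           kappa = kappa,
                           seed = childSeed(seed, 31 * match(holdout, sites)))
    recs[[holdout]] <- data.frame(
      site_heldout = holdout, theta = theta, kappa = kappa, gated = gated,
      auc = empiricalAuc(sc, lab[testRows]),
      n_test = sum(testRows),
      features = paste(feats, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  new("EvaluationReport", task = task, records = do.call(rbind, recs),
      seed = as.numeric(seed),
      config = list(k = k, piThreshold = piThreshold, alpha = alpha,
                    piMode = piMode, sfsIterations = sfsIterations))
}

#' Percent improvement of gated over ungated selection
#'
#' `100 * (aucSd - aucD) / aucD`; positive iff the stability-gated model
#' wins. Computed from unrounded AUCs.
#'
#' @param aucSd mean AUC of the gated (FS_sd) model.
#' @param aucD mean AUC of the ungated (FS_d) model (must be > 0).
#' @return Percent improvement.
#' @export
percentImprovement <- function(aucSd, aucD) {
  stopifnot(aucD > 0)
  100 * (aucSd - aucD) / aucD
}

#' Full selector-by-classifier evaluation grid
#'
#' Runs [holdOneSiteOut()] for every combination of the requested selectors
#' and classifiers, gated and ungated, and tabulates mean (std) AUC and the
#' percent improvement of FS_sd over FS_d per cell.
#'
#' @param table a [FeatureTable-class].
#' @param task `"cancer"` or `"gleason"`.
#' @param thetas,kappas selector and classifier ids.
#' @param ... passed to [holdOneSiteOut()].
#' @param seed integer seed.
#' @return An [EvaluationReport-class] whose records stack all folds; use
#'   [summarizeReport()] for the theta x kappa grid.
#' @export
evaluationGrid <- function(table, task = c("cancer", "gleason"),
                           thetas = c("SFS", "WLCX", "mRMR", "ROC"),
                           kappas = c("LDA", "QDA", "SVM", "RF"),
                           seed = 1L, ...) {
  task <- match.arg(task)
  all <- list()
  for (th in thetas) for (ka in kappas) for (g in c(TRUE, FALSE)) {
    rep <- holdOneSiteOut(table, task = task, theta = th, kappa = ka,
                          gated = g, seed = seed, ...)
    all[[length(all) + 1L]] <- reportRecords(rep)
  }
  new("EvaluationReport", task = task, records = do.call(rbind, all),
      seed = as.numeric(seed), config = list(thetas = thetas,
                                             kappas = kappas))
}

#' Summarize an evaluation report into the selector-by-classifier table
#'
#' @param report an [EvaluationReport-class] from [evaluationGrid()].
#' @return data.frame with one row per (theta, kappa): mean and std AUC for
#'   FS_sd and FS_d and the percent improvement.
#' @export
summarizeReport <- function(report) {
  r <- reportRecords(report)
  cells <- unique(r[, c("theta", "kappa")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    th <- cells$theta[i]; ka <- cells$kappa[i]
    sd_ <- r$auc[r$theta == th & r$kappa == ka & r$gated]
    d_ <- r$auc[r$theta == th & r$kappa == ka & !r$gated]
    data.frame(theta = th, kappa = ka,
               auc_sd_mean = mean(sd_), auc_sd_std = sd(sd_),
               auc_d_mean = mean(d_), auc_d_std = sd(d_),
               pct_improvement = percentImprovement(mean(sd_), mean(d_)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Effect of normalization on feature instability
#'
#' Computes PI on two feature tables of the same regions (before and after
#' color normalization) with an identical protocol and reports the
#' per-feature PI delta (post minus pre) and per-family mean PI before and
#' after.
#'
#' @param tablePre,tablePost [FeatureTable-class] objects with identical
#'   region sets and feature sets.
#' @param alpha,piMode,seed PI protocol.
#' @return list with `perFeature` (data.frame: feature, family, pi_pre,
#'   pi_post, delta) and `perFamily` (data.frame: family, pi_pre, pi_post).
#' @export
normalizationEffect <- function(tablePre, tablePost, alpha = 0.05,
                                piMode = "exact", seed = 1L) {
  if (!identical(sort(colnames(tablePre)), sort(colnames(tablePost))) ||
      !identical(rownames(tablePre), rownames(tablePost)))
    stop("pre/post tables must cover the same regions and features")
  pre <- preparationInstability(tablePre, alpha = alpha, mode = piMode,
                                seed = seed)
  post <- preparationInstability(tablePost, alpha = alpha, mode = piMode,
                                 seed = seed)
  fam <- featureFamilies(tablePre)
  pf <- data.frame(feature = names(piValues(pre)),
                   family = unname(fam[names(piValues(pre))]),
                   pi_pre = unname(piValues(pre)),
                   pi_post = unname(piValues(post)[names(piValues(pre))]),
                   stringsAsFactors = FALSE)
  pf$delta <- pf$pi_post - pf$pi_pre
  fams <- unique(pf$family)
  pfam <- data.frame(
    family = fams,
    pi_pre = vapply(fams, function(f)
      mean(pf$pi_pre[which(pf$family %in% f)]), numeric(1)),
    pi_post = vapply(fams, function(f)
      mean(pf$pi_post[which(pf$family %in% f)]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(perFeature = pf, perFamily = pfam)
}
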