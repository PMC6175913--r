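# Feature selection: the stability gate and the four selectors (SFS with a
# seeded 10 x 3-fold QDA CV-AUC objective, Wilcoxon rank-sum, mRMR with
# quartile-binned mutual information, empirical-ROC ranking).

#' Empirical AUC of a feature against binary labels
#'
#' Area under the empirical receiver operating characteristic curve obtained
#' by sweeping a threshold over the feature values; equal to the rank-sum
#' (Mann-Whitney U) statistic divided by `n1 * n0`, with ties contributing
#' one half. Orientation is as-given (no flipping): perfectly
#' anti-correlated values give 0.
#'
#' @param values numeric feature values (scores).
#' @param labels binary labels (see [fitPredictScores()] conventions).
#' @return AUC in `[0, 1]`.
#' @export
empiricalAuc <- function(values, labels) {
  y <- asBinary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stability gate
#'
#' Returns exactly the candidate features whose PI is strictly below the
#' threshold (features with PI at or above the predetermined threshold are
#' excluded from consideration).
#'
#' @param candidates character vector of feature names.
#' @param profile an [InstabilityProfile-class] covering every candidate.
#' @param threshold PI threshold (default 0.25).
#' @return Character vector of surviving candidates (original order).
#' @export
stabilityGate <- function(candidates, profile, threshold = 0.25) {
  piv <- piValues(profile)
  miss <- setdiff(candidates, names(piv))
  if (length(miss))
    stop("no PI value for candidate(s): ", paste(head(miss, 5), collapse = ", "))
  out <- candidates[piv[candidates] < threshold]
  if (!length(out)) stop("no features pass the stability gate")
  out
}

# mutual information between two discrete vectors (log2)
discreteMI <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  sel <- p > 0
  sum(p[sel] * log2(p[sel] / e[sel]))
}

# equal-frequency quartile binning; constant features collapse to one bin
quartileBin <- function(x) {
  br <- unique(quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Select features by one of the four study selectors
#'
#' * `SFS`: greedy forward addition maximizing the mean AUC of the growing
#'   set under quadratic discriminant analysis in 10 seeded iterations of
#'   3-fold cross validation (joint-set objective).
#' * `WLCX`: ranks features by the absolute difference between the observed
#'   positive-class rank sum and its null expectation.
#' * `mRMR`: greedy maximum relevance (mutual information with the class,
#'   quartile-binned) minus mean redundancy with already selected features
#'   (MID form).
#' * `ROC`: top features by orientation-corrected empirical AUC,
#'   `max(AUC, 1 - AUC)`.
#'
#' Ties are broken by canonical (input) feature order; constant features are
#' scored with their documented degenerate values, never crash.
#'
#' @param table a [FeatureTable-class] training split (or a plain numeric
#'   matrix regions x features).
#' @param labels binary task labels, one per region (rows with `NA` are
#'   dropped).
#' @param theta selector id: `"SFS"`, `"WLCX"`, `"mRMR"` or `"ROC"`.
#' @param k number of features to select (default 5).
#' @param candidates optional candidate subset (e.g. the stability-gate
#'   survivors); defaults to all features.
#' @param seed integer seed (SFS objective).
#' @param sfsIterations,sfsFolds SFS objective CV protocol.
#' @param gated,piThreshold bookkeeping recorded on the result.
#' @return A [SelectionResult-class].
#' @export
selectFeatures <- function(table, labels, theta = c("ROC", "WLCX", "mRMR", "SFS"),
                           k = 5L, candidates = NULL, seed = 1L,
                           sfsIterations = 10L, sfsFolds = 3L,
                           gated = FALSE, piThreshold = NA_real_) {
  theta <- match.arg(theta)
  X <- if (is(table, "FeatureTable")) t(featureValues(table)) else as.matrix(table)
  keep <- !is.na(labels)
  X <- X[keep, , drop = FALSE]
  y <- asBinary(labels[keep])
  if (length(unique(y)) < 2L) stop("both classes required for selection")
  if (is.null(candidates)) candidates <- colnames(X)
  X <- X[, candidates, drop = FALSE]
  if (ncol(X) < k) stop("fewer candidate features than k")

  scores <- setNames(rep(NA_real_, ncol(X)), candidates)
  if (theta == "ROC") {
    a <- apply(X, 2, empiricalAuc, labels = y)
    scores <- pmax(a, 1 - a)
    sel <- candidates[order(-scores, seq_along(scores))[seq_len(k)]]
  } else if (theta == "WLCX") {
    n1 <- sum(y == 1); n <- length(y)
    expW <- n1 * (n + 1) / 2
    scores <- apply(X, 2, function(v) abs(sum(rank(v)[y == 1]) - expW))
    sel <- candidates[order(-scores, seq_along(scores))[seq_len(k)]]
  } else if (theta == "mRMR") {
    bins <- apply(X, 2, quartileBin)
    rel <- apply(bins, 2, discreteMI, b = y)
    selIdx <- integer(0)
    for (step in seq_len(k)) {
      remaining <- setdiff(seq_len(ncol(X)), selIdx)
      crit <- vapply(remaining, function(j) {
        red <- if (length(selIdx))
          mean(vapply(selIdx, function(i2)
            discreteMI(bins[, j], bins[, i2]), numeric(1)))
        else 0
        rel[j] - red
      }, numeric(1))
      pick <- remaining[order(-crit, remaining)[1]]
      scores[pick] <- crit[match(pick, remaining)]
      selIdx <- c(selIdx, pick)
    }
    sel <- candidates[selIdx]
  } else { # SFS
    foldMat <- makeFoldMatrix(y, sfsIterations, sfsFolds, seed)
    selIdx <- integer(0)
    for (step in seq_len(k)) {
      remaining <- setdiff(seq_len(ncol(X)), selIdx)
      objs <- vapply(remaining, function(j) {
        cvAucFast(X[, c(selIdx, j), drop = FALSE], y, foldMat, kappa = "QDA")
      }, numeric(1))
      pick <- remaining[order(-objs, remaining)[1]]
      scores[pick] <- max(objs)
      selIdx <- c(selIdx, pick)
    }
    sel <- candidates[selIdx]
  }
  new("SelectionResult", features = sel, scores = scores, theta = theta,
      gated = gated, piThreshold = piThreshold, seed = as.numeric(seed))
}
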