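# Classifier wrappers: LDA/QDA as Gaussian discriminants with a documented
# ridge-regularized covariance (so singular within-class covariances never
# crash), linear-kernel SVM (unit cost) via e1071, and a 100-tree random
# forest. Scores are continuous and oriented so that larger means more
# likely positive class.

ridgeChol <- function(S, base = 1e-6) {
  lam <- base * mean(diag(S)) + 1e-12
  for (i in 1:30) {
    ch <- tryCatch(chol(S + diag(lam, nrow(S))), error = function(e) NULL)
    if (!is.null(ch)) {
      if (i > 1L)
        warning("covariance required extra ridge regularization (lambda = ",
                signif(lam, 3), ")")
      return(ch)
    }
    lam <- lam * 10
  }
  stop("covariance matrix could not be regularized")
}

fastLdaFit <- function(X, y) {
  X0 <- X[y == 0, , drop = FALSE]; X1 <- X[y == 1, , drop = FALSE]
  m0 <- colMeans(X0); m1 <- colMeans(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  Sp <- (crossprod(sweep(X0, 2, m0)) + crossprod(sweep(X1, 2, m1))) /
    max(1, (n0 + n1 - 2))
  ch <- ridgeChol(Sp)
  w <- backsolve(ch, backsolve(ch, m1 - m0, transpose = TRUE))
  list(w = w, b = -sum(w * (m0 + m1)) / 2)
}

fastLdaScore <- function(fit, X) as.numeric(X %*% fit$w + fit$b)

gaussLogDens <- function(X, m, ch) {
  Z <- forwardsolve(t(ch), t(sweep(X, 2, m)))
  -colSums(Z^2) / 2 - sum(log(diag(ch)))
}

fastQdaFit <- function(X, y) {
  X0 <- X[y == 0, , drop = FALSE]; X1 <- X[y == 1, , drop = FALSE]
  covOf <- function(M) {
    if (nrow(M) < 2L) return(diag(1, ncol(M)))
    cov(M)
  }
  list(m0 = colMeans(X0), m1 = colMeans(X1),
       ch0 = ridgeChol(covOf(X0)), ch1 = ridgeChol(covOf(X1)),
       lp = log(nrow(X1) / nrow(X0)))
}

fastQdaScore <- function(fit, X) {
  gaussLogDens(X, fit$m1, fit$ch1) - gaussLogDens(X, fit$m0, fit$ch0) + fit$lp
}

#' Fit a classifier and score test rows
#'
#' Trains one of the four study classifiers on `(trainX, trainY)` and
#' returns a continuous score per test row (larger = more likely positive).
#' LDA/QDA are Gaussian discriminants with a ridge-regularized covariance;
#' SVM is a linear kernel with unit cost; RF is a 100-tree random forest
#' scored by the positive-class vote fraction. Features are standardized
#' with training mean/variance for LDA/QDA/SVM.
#'
#' @param trainX,trainY training matrix and binary labels (0/1, logical, or
#'   a two-level factor whose second level is positive). Both classes must
#'   be present.
#' @param testX test matrix (same columns).
#' @param kappa one of `"LDA"`, `"QDA"`, `"SVM"`, `"RF"`.
#' @param seed integer seed (needed by RF).
#' @return Numeric score per test row.
#' @export
fitPredictScores <- function(trainX, trainY, testX, kappa = "LDA",
                             seed = 1L) {
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  y <- asBinary(trainY)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  if (!kappa %in% c("LDA", "QDA", "SVM", "RF"))
    stop("unknown classifier kappa: ", kappa)
  if (kappa %in% c("LDA", "QDA", "SVM")) {
    mu <- colMeans(trainX)
    sdv <- apply(trainX, 2, sd); sdv[sdv == 0] <- 1
    trainX <- sweep(sweep(trainX, 2, mu), 2, sdv, "/")
    testX <- sweep(sweep(testX, 2, mu), 2, sdv, "/")
  }
  switch(kappa,
    LDA = fastLdaScore(fastLdaFit(trainX, y), testX),
    QDA = fastQdaScore(fastQdaFit(trainX, y), testX),
    SVM = {
      fy <- factor(y, levels = c(0, 1))
      fit <- e1071::svm(trainX, fy, kernel = "linear", cost = 1,
                        scale = FALSE)
      pr <- stats::predict(fit, testX, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision values favor the class named first in the column label
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      if (first == "1") as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
    },
    RF = {
      fy <- factor(y, levels = c(0, 1))
      rf <- withr::with_seed(as.integer(seed),
        randomForest::randomForest(trainX, fy, ntree = 100L))
      stats::predict(rf, testX, type = "prob")[, "1"]
    })
}

asBinary <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) return(as.integer(y == levels(y)[2]))
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (length(u) > 2L) stop("labels must be binary")
    return(as.integer(y == max(u)))
  }
  f <- factor(y)
  as.integer(f == levels(f)[2])
}

# stratified fold assignments for repeated k-fold CV: an n x iterations
# integer matrix, a pure function of (y, iterations, folds, seed)
makeFoldMatrix <- function(y, iterations, folds, seed) {
  n <- length(y)
  withr::with_seed(as.integer(seed), {
    out <- matrix(0L, n, iterations)
    for (it in seq_len(iterations)) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        out[idx, it] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    }
    out
  })
}

# AUC of scores against 0/1 labels without input coercion (inner loops)
rankAuc <- function(sc, y01) {
  n1 <- sum(y01); n0 <- length(y01) - n1
  r <- rank(sc)
  (sum(r[y01 == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# fast repeated-CV AUC for the Gaussian discriminants (both are affine
# equivariant, so the train-split standardization applied by
# fitPredictScores is a no-op for their rankings and is skipped here)
cvAucFast <- function(X, y01, foldMat, kappa = c("QDA", "LDA")) {
  kappa <- match.arg(kappa)
  folds <- max(foldMat)
  aucs <- numeric(0)
  for (it in seq_len(ncol(foldMat))) {
    for (fo in seq_len(folds)) {
      te <- foldMat[, it] == fo
      ytr <- y01[!te]; yte <- y01[te]
      if (!any(yte == 1L) || !any(yte == 0L) ||
          !any(ytr == 1L) || !any(ytr == 0L)) next
      Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      sc <- if (kappa == "QDA") fastQdaScore(fastQdaFit(Xtr, ytr), Xte)
            else fastLdaScore(fastLdaFit(Xtr, ytr), Xte)
      aucs <- c(aucs, rankAuc(sc, yte))
    }
  }
  if (!length(aucs)) return(NA_real_)
  mean(aucs)
}

# mean AUC over repeated stratified k-fold cross validation; the workhorse
# behind the per-feature PI-AUC map and the SFS objective
cvAuc <- function(X, y, kappa = "LDA", iterations = 10L, folds = 3L,
                  seed = 1L) {
  X <- as.matrix(X)
  y <- asBinary(y)
  foldMat <- makeFoldMatrix(y, iterations, folds, seed)
  if (kappa %in% c("LDA", "QDA"))
    return(cvAucFast(X, y, foldMat, kappa = kappa))
  aucs <- numeric(0)
  for (it in seq_len(iterations)) {
    for (fo in seq_len(folds)) {
      te <- foldMat[, it] == fo
      if (length(unique(y[te])) < 2L || length(unique(y[!te])) < 2L) next
      sc <- fitPredictScores(X[!te, , drop = FALSE], y[!te],
                             X[te, , drop = FALSE], kappa = kappa,
                             seed = childSeed(seed, it * folds + fo))
      aucs <- c(aucs, empiricalAuc(sc, y[te]))
    }
  }
  if (!length(aucs)) return(NA_real_)
  mean(aucs)
}

taskLabels <- function(table, task = c("cancer", "gleason")) {
  task <- match.arg(task)
  cls <- regionInfo(table)$class
  if (task == "cancer") {
    out <- rep(NA_integer_, length(cls))
    out[cls == "noncancer"] <- 0L
    out[cls == "cancer"] <- 1L
  } else {
    out <- rep(NA_integer_, length(cls))
    out[cls == "gleason3"] <- 0L
    out[cls == "gleason4"] <- 1L
  }
  out
}
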