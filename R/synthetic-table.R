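# Multi-site synthetic feature tables with known discriminative and
# site-shifted (unstable) structure. Baseline feature values are i.i.d.
# standard normal (or lognormal) across sites; designated discriminative
# features receive a class mean shift (in within-class standard deviations);
# designated unstable features receive per-site location (and optionally
# scale) shifts. Discriminative and unstable sets may overlap -- that overlap
# is exactly what the stability gate exists to reject.

#' Bundled synthetic grading-study table
#'
#' A 4-site Gleason-3 vs Gleason-4 analogue of the evaluation study: 40
#' regions per site (28 grade-labelled at even balance plus 12 non-cancerous
#' rows for the PI protocol), 60 features of which six carry a 1-sigma grade
#' effect, six carry 3-sigma site shifts, and two of the discriminative
#' features are additionally site-shifted (the overlap the stability gate
#' must reject).
#'
#' @param seed integer seed.
#' @return A [FeatureTable-class].
#' @export
demoGleasonTable <- function(seed = 1L) {
  sh <- matrix(0, 8, 4, dimnames = list(as.character(5:12), NULL))
  sh["7", c(1, 3)] <- 3;  sh["8", 2] <- 3
  sh["9", 4] <- 3;        sh["10", c(2, 4)] <- 3
  sh["11", 1] <- 3;       sh["12", c(1, 4)] <- 3
  sh["5", 4] <- 2;        sh["6", 1] <- 2   # discriminative AND unstable
  simulateFeatureTable(nSites = 4L, nRegionsPerSite = 28L, nFeatures = 60L,
                       classBalance = 0.5,
                       classes = c("gleason3", "gleason4"),
                       nNoncancerPerSite = 12L,
                       discriminative = setNames(rep(1, 6), as.character(1:6)),
                       siteShifts = sh, seed = seed)
}

#' Simulate a multi-site feature table
#'
#' @param nSites number of sites.
#' @param nRegionsPerSite regions per site (class-labelled rows).
#' @param nFeatures number of features.
#' @param classBalance fraction of class-labelled rows in the positive
#'   (second) class; a scalar or one value per site. Per-site balances allow
#'   site-class confounding, the mechanism by which unstable features can
#'   carry spurious pooled-training separation.
#' @param classes length-2 character vector `(negative, positive)`
#'   (default `c("noncancer", "cancer")`).
#' @param nNoncancerPerSite extra `"noncancer"` baseline rows per site (used
#'   for the PI protocol when `classes` does not include `"noncancer"`,
#'   e.g. the Gleason grading task).
#' @param discriminative named numeric vector: names are feature indices,
#'   values are class effect sizes in within-class standard deviations.
#' @param unstable named numeric vector: names are feature indices, values
#'   are site shift magnitudes in baseline standard deviations. By default
#'   each unstable feature is shifted by its magnitude in the last site
#'   only; pass `siteShifts` for full control.
#' @param siteShifts optional numeric matrix (rows named by feature index,
#'   `nSites` columns) of per-site location shifts; overrides `unstable`.
#' @param siteScales optional matrix like `siteShifts` with per-site scale
#'   multipliers.
#' @param noiseFamily `"gaussian"` or `"lognormal"` (effects applied on the
#'   log scale, then exponentiated).
#' @param regionsPerPatient regions per synthetic patient (default 1).
#' @param seed integer seed; the generator is a pure function of its
#'   parameters and the seed.
#' @return A [FeatureTable-class]; `metadata()` carries the ground truth
#'   (`discriminative`, `unstable` feature names and the generating spec).
#' @export
simulateFeatureTable <- function(nSites = 4L, nRegionsPerSite = 40L,
                                 nFeatures = 20L, classBalance = 0.5,
                                 classes = c("noncancer", "cancer"),
                                 nNoncancerPerSite = 0L,
                                 discriminative = NULL, unstable = NULL,
                                 siteShifts = NULL, siteScales = NULL,
                                 noiseFamily = c("gaussian", "lognormal"),
                                 regionsPerPatient = 1L, seed = 1L) {
  noiseFamily <- match.arg(noiseFamily)
  stopifnot(nSites >= 1L, nRegionsPerSite >= 1L, nFeatures >= 1L,
            length(classes) == 2L)
  if (length(classBalance) == 1L) classBalance <- rep(classBalance, nSites)
  stopifnot(length(classBalance) == nSites,
            all(classBalance > 0 & classBalance < 1))

  checkIdx <- function(v, what) {
    idx <- as.integer(names(v))
    if (any(is.na(idx)) || any(idx < 1L | idx > nFeatures))
      stop("invalid ", what, " feature indices")
    idx
  }
  discIdx <- if (length(discriminative)) checkIdx(discriminative,
                                                  "discriminative") else integer(0)
  shiftMat <- matrix(0, nFeatures, nSites)
  if (!is.null(siteShifts)) {
    idx <- as.integer(rownames(siteShifts))
    if (any(is.na(idx)) || any(idx < 1L | idx > nFeatures) ||
        ncol(siteShifts) != nSites)
      stop("invalid siteShifts specification")
    shiftMat[idx, ] <- as.matrix(siteShifts)
  } else if (length(unstable)) {
    idx <- checkIdx(unstable, "unstable")
    shiftMat[cbind(idx, nSites)] <- as.numeric(unstable)
  }
  scaleMat <- matrix(1, nFeatures, nSites)
  if (!is.null(siteScales)) {
    idx <- as.integer(rownames(siteScales))
    if (any(is.na(idx)) || any(idx < 1L | idx > nFeatures) ||
        ncol(siteScales) != nSites)
      stop("invalid siteScales specification")
    scaleMat[idx, ] <- as.matrix(siteScales)
  }

  siteNames <- sprintf("site%02d", seq_len(nSites))
  rowsPerSite <- nRegionsPerSite + nNoncancerPerSite

  withr::with_seed(as.integer(seed), {
    rows <- list(); info <- list()
    patientCounter <- 0L
    for (s in seq_len(nSites)) {
      nPos <- round(classBalance[s] * nRegionsPerSite)
      cls <- c(rep(classes[2], nPos), rep(classes[1], nRegionsPerSite - nPos),
               rep("noncancer", nNoncancerPerSite))
      X <- matrix(rnorm(rowsPerSite * nFeatures), rowsPerSite, nFeatures)
      # per-site location/scale shifts on unstable features
      X <- sweep(X, 2, scaleMat[, s], "*")
      X <- sweep(X, 2, shiftMat[, s], "+")
      # class effect on discriminative features (positive class only,
      # applied to class-labelled rows)
      if (length(discIdx)) {
        pos <- which(cls == classes[2])
        for (j in seq_along(discIdx))
          X[pos, discIdx[j]] <- X[pos, discIdx[j]] +
            as.numeric(discriminative[j])
      }
      if (noiseFamily == "lognormal") X <- exp(X)
      nPatients <- ceiling(rowsPerSite / regionsPerPatient)
      pid <- rep(seq_len(nPatients), each = regionsPerPatient)[
        seq_len(rowsPerSite)] + patientCounter
      patientCounter <- patientCounter + nPatients
      rows[[s]] <- X
      info[[s]] <- data.frame(
        region_id = sprintf("%s_r%03d", siteNames[s], seq_len(rowsPerSite)),
        patient_id = sprintf("p%04d", pid),
        site = siteNames[s],
        class = cls,
        stringsAsFactors = FALSE)
    }
  })
  X <- do.call(rbind, rows)
  info <- do.call(rbind, info)
  featNames <- sprintf("f%03d", seq_len(nFeatures))
  values <- t(X)
  rownames(values) <- featNames
  colnames(values) <- info$region_id
  unstableIdx <- which(apply(shiftMat != 0, 1, any) |
                         apply(scaleMat != 1, 1, any))
  FeatureTable(values, info,
               metadata = list(
                 discriminative = featNames[discIdx],
                 unstable = featNames[unstableIdx],
                 site_shifts = shiftMat,
                 spec = list(nSites = nSites,
                             nRegionsPerSite = nRegionsPerSite,
                             nFeatures = nFeatures,
                             classBalance = classBalance,
                             classes = classes,
                             nNoncancerPerSite = nNoncancerPerSite,
                             noiseFamily = noiseFamily, seed = seed)))
}
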