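# Preparation-induced instability (PI): the rate at which a feature is
# observed to be significantly different in distribution between sites'
# non-cancerous regions (two-sided Wilcoxon rank-sum). Latent instability
# (LI) is the within-site baseline: the rejection rate over random
# half-splits of a single site.

rankSumP <- function(x, y) {
  p <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))$p.value
  # fully tied (e.g. constant) samples yield NA: no evidence of a difference
  if (is.na(p)) 1 else p
}

#' Preparation-induced instability (PI) per feature
#'
#' In exact mode, every unordered site pair is compared per feature with a
#' two-sided Wilcoxon rank-sum test and PI is the fraction of pairs with
#' `p < alpha` (values are multiples of `1/choose(m, 2)` for `m` sites). In
#' subsampled mode, `repetitions` random subsamples of `subsampleSize`
#' regions per site are drawn without replacement and PI is the fraction of
#' (pair, repetition) rejections.
#'
#' @param table a [FeatureTable-class]. PI is conventionally computed on
#'   non-cancerous regions; set `restrictClass = "noncancer"` (default) to
#'   enforce that, or `NULL` to use all rows.
#' @param alpha significance level (default 0.05).
#' @param mode `"exact"` or `"subsampled"`.
#' @param repetitions,subsampleSize subsampled-mode protocol.
#' @param seed integer seed (subsampled mode).
#' @param restrictClass class label to restrict rows to, or `NULL`.
#' @return An [InstabilityProfile-class].
#' @export
preparationInstability <- function(table, alpha = 0.05,
                                   mode = c("exact", "subsampled"),
                                   repetitions = 100L, subsampleSize = NULL,
                                   seed = 1L, restrictClass = "noncancer") {
  mode <- match.arg(mode)
  vals <- featureValues(table)
  info <- regionInfo(table)
  if (!is.null(restrictClass)) {
    keep <- info$class %in% restrictClass
    vals <- vals[, keep, drop = FALSE]
    info <- info[keep, , drop = FALSE]
  }
  sites <- sort(unique(info$site))
  if (length(sites) < 2L) stop("need at least 2 sites")
  nPer <- table(info$site)
  small <- names(nPer)[nPer < 4L]
  if (length(small))
    stop("site(s) with fewer than 4 regions: ", paste(small, collapse = ", "))
  bySite <- lapply(sites, function(s) vals[, info$site == s, drop = FALSE])
  pairs <- utils::combn(length(sites), 2)

  pivals <- if (mode == "exact") {
    rej <- matrix(FALSE, nrow(vals), ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      a <- bySite[[pairs[1, p]]]; b <- bySite[[pairs[2, p]]]
      rej[, p] <- vapply(seq_len(nrow(vals)), function(f)
        rankSumP(a[f, ], b[f, ]) < alpha, logical(1))
    }
    rowMeans(rej)
  } else {
    if (is.null(subsampleSize))
      subsampleSize <- max(4L, floor(min(nPer) / 2))
    if (subsampleSize > min(nPer))
      stop("subsampleSize exceeds the smallest site")
    tot <- matrix(0, nrow(vals), ncol(pairs))
    withr::with_seed(as.integer(seed), {
      for (r in seq_len(repetitions)) {
        sub <- lapply(bySite, function(m)
          m[, sample.int(ncol(m), subsampleSize), drop = FALSE])
        for (p in seq_len(ncol(pairs))) {
          a <- sub[[pairs[1, p]]]; b <- sub[[pairs[2, p]]]
          tot[, p] <- tot[, p] + vapply(seq_len(nrow(vals)), function(f)
            rankSumP(a[f, ], b[f, ]) < alpha, numeric(1))
        }
      }
    })
    rowMeans(tot) / repetitions
  }
  new("InstabilityProfile",
      pi = setNames(pivals, rownames(vals)),
      protocol = list(mode = mode, alpha = alpha,
                      repetitions = if (mode == "subsampled") repetitions else NA,
                      subsample_size = if (mode == "subsampled") subsampleSize else NA,
                      seed = seed, restrict_class = restrictClass),
      sites = sites)
}

#' Latent instability (LI) per feature within one site
#'
#' The images of a single site are randomly split in half `repetitions`
#' times; LI is the fraction of splits in which the two halves' feature
#' distributions differ by a Wilcoxon rank-sum test at level `alpha`. For an
#' i.i.d. feature LI converges to `alpha`.
#'
#' @param table a [FeatureTable-class] restricted to (or containing) one
#'   site.
#' @param site site id to use (default: the only site present).
#' @param repetitions number of random half-splits.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return Named numeric vector of per-feature LI values.
#' @export
latentInstability <- function(table, site = NULL, repetitions = 100L,
                              alpha = 0.05, seed = 1L) {
  vals <- featureValues(table)
  info <- regionInfo(table)
  if (is.null(site)) {
    sites <- unique(info$site)
    if (length(sites) != 1L)
      stop("multiple sites present; specify `site`")
    site <- sites
  }
  vals <- vals[, info$site == site, drop = FALSE]
  n <- ncol(vals)
  if (n < 8L) stop("need at least 8 regions for half-splitting")
  half <- n %/% 2L
  rej <- numeric(nrow(vals))
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(repetitions)) {
      a <- sample.int(n, half)
      rej <- rej + vapply(seq_len(nrow(vals)), function(f)
        rankSumP(vals[f, a], vals[f, -a]) < alpha, numeric(1))
    }
  })
  setNames(rej / repetitions, rownames(vals))
}

#' Gland-removal perturbation experiment
#'
#' Removes 0 to `maxRemovalPct` percent of the glands in `stepPct`
#' increments; at every level `simsPerLevel` random gland subsets are
#' removed, the 216 gland-derived features are recomputed, and the percent
#' change against the unperturbed vector is recorded. Percent change is
#' `|(f - f0)/f0| * 100`, falling back to `|f - f0| * 100` when `f0 = 0`.
#' Texture (Haralick) features do not depend on the gland set and are not
#' recomputed. Features undefined after removal (e.g. fewer than 4 glands)
#' are flagged `NA`, not fabricated.
#'
#' @param roi the source [RoiImage-class] (provenance only).
#' @param glands the [GlandSet-class] to perturb (needs >= 10 glands).
#' @param maxRemovalPct,stepPct removal grid in percent (defaults 20 and 1,
#'   giving 21 levels).
#' @param simsPerLevel random subsets per level (default 10).
#' @param seed integer seed.
#' @param config configuration list.
#' @return A list with `levels` (percent), `pctChange` (features x levels x
#'   sims array) and `meanPctChange` (features x levels matrix).
#' @export
glandRemovalPerturbation <- function(roi, glands, maxRemovalPct = 20,
                                     stepPct = 1, simsPerLevel = 10L,
                                     seed = 1L, config = defaultConfig()) {
  n <- glandCount(glands)
  if (n < 10L) stop("perturbation experiment needs at least 10 glands")
  levels <- seq(0, maxRemovalPct, by = stepPct)
  baseMeas <- shapeMeasurements(glands, featMpp = config$feat_mpp)
  baseAngles <- vapply(boundaries(glands, units = "um"), glandOrientation,
                       numeric(1))
  cenUm <- centroids(glands, units = "um")

  glandFeats <- function(keep) {
    cen <- cenUm[keep, , drop = FALSE]
    part <- buildSubgraphs(cen, config$subgraph_radius_um)
    gg <- globalGraphFeatures(cen)
    meas <- baseMeas[keep, , drop = FALSE]
    shp <- numeric(0)
    for (m in shapeMeasurementNames) {
      a <- aggregateShape(meas[, m])
      names(a) <- paste0("shape_", shapeAggNames, "_", m)
      shp <- c(shp, a)
    }
    bins <- orientationBin(baseAngles[keep])
    statRows <- list()
    for (ci in unique(part$membership)) {
      memb <- which(part$membership == ci)
      if (length(memb) < 2L) next
      statRows[[length(statRows) + 1L]] <-
        cooccurrenceStats(orientationCooccurrence(bins[memb]))
    }
    dis <- if (length(statRows)) {
      S <- do.call(rbind, statRows)
      out <- numeric(0)
      for (s in glcmStatNames)
        out <- c(out, mean(S[, s]),
                 if (nrow(S) > 1L) sd(S[, s]) else 0, diff(range(S[, s])))
      setNames(out, disorderFeatureNames())
    } else setNames(rep(0, 39), disorderFeatureNames())
    c(gg, shp, dis, subgraphFeatures(part))
  }

  f0 <- glandFeats(seq_len(n))
  nf <- length(f0)
  pct <- array(NA_real_, c(nf, length(levels), simsPerLevel),
               dimnames = list(names(f0), paste0("pct", levels), NULL))
  withr::with_seed(as.integer(seed), {
    for (li in seq_along(levels)) {
      nRemove <- round(n * levels[li] / 100)
      for (s in seq_len(simsPerLevel)) {
        keep <- if (nRemove == 0L) seq_len(n)
                else setdiff(seq_len(n), sample.int(n, nRemove))
        f <- tryCatch(glandFeats(keep), error = function(e) NULL)
        if (is.null(f)) next  # undefined: stays NA
        delta <- ifelse(f0 == 0, abs(f - f0), abs((f - f0) / f0)) * 100
        pct[, li, s] <- delta
      }
    }
  })
  list(levels = levels, pctChange = pct,
       meanPctChange = apply(pct, c(1, 2), mean, na.rm = FALSE))
}

#' Map features into PI-AUC space
#'
#' For every feature, a single-feature LDA classifier is evaluated with
#' `cvIterations` iterations of `folds`-fold cross validation separately per
#' site; the mean AUC across sites is paired with the feature's PI computed
#' from the non-cancerous regions.
#'
#' @param table a [FeatureTable-class].
#' @param task `"cancer"` (cancer vs non-cancer) or `"gleason"`
#'   (gleason3 vs gleason4).
#' @param cvIterations,folds cross-validation protocol (defaults 100 and 3).
#' @param alpha,piMode,seed PI protocol and seed.
#' @return data.frame with columns `feature`, `family`, `pi`, `mean_auc`
#'   and one `auc_<site>` column per site.
#' @export
piAucMap <- function(table, task = c("cancer", "gleason"),
                     cvIterations = 100L, folds = 3L, alpha = 0.05,
                     piMode = "exact", seed = 1L) {
  task <- match.arg(task)
  lab <- taskLabels(table, task)
  vals <- featureValues(table)[, !is.na(lab), drop = FALSE]
  info <- regionInfo(table)[!is.na(lab), , drop = FALSE]
  y <- lab[!is.na(lab)]
  sites <- sort(unique(info$site))
  for (s in sites)
    if (length(unique(y[info$site == s])) < 2L)
      stop("site with a single class: ", s)

  prof <- preparationInstability(table, alpha = alpha, mode = piMode,
                                 seed = seed)
  aucMat <- matrix(NA_real_, nrow(vals), length(sites),
                   dimnames = list(rownames(vals), sites))
  for (si in seq_along(sites)) {
    sel <- info$site == sites[si]
    Xs <- vals[, sel, drop = FALSE]
    ys <- asBinary(y[sel])
    foldMat <- makeFoldMatrix(ys, cvIterations, folds,
                              seed = childSeed(seed, si))
    for (f in seq_len(nrow(vals))) {
      aucMat[f, si] <- cvAucFast(matrix(Xs[f, ], ncol = 1), ys, foldMat,
                                 kappa = "LDA")
    }
  }
  fam <- featureFamilies(table)
  data.frame(feature = rownames(vals),
             family = unname(fam[rownames(vals)]),
             pi = unname(piValues(prof)[rownames(vals)]),
             mean_auc = rowMeans(aucMat),
             setNames(as.data.frame(aucMat), paste0("auc_", sites)),
             row.names = NULL, stringsAsFactors = FALSE)
}
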