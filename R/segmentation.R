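# Lumen-based gland segmentation: k-means (k = 4) on 10,000 sampled pixels
# labels every pixel nuclei/cytoplasm/stroma/lumen by its nearest RGB
# centroid; connected lumen components are grown to the surrounding nuclear
# ring and their smoothed boundaries become gland polygons.

tissueLabelNames <- c("nuclei", "cytoplasm", "stroma", "lumen")

#' Classify tissue pixels by k-means in RGB space
#'
#' Fits k = 4 centroids (Lloyd iterations, 10 restarts, best inertia kept)
#' on up to `nSamples` randomly chosen pixels, then labels every pixel with
#' its nearest centroid (ties broken by the lowest centroid index). Labels
#' are assigned by the documented rule: lumen is the brightest centroid
#' (highest mean RGB), nuclei the darkest, and of the remaining two the more
#' saturated is stroma, the less saturated cytoplasm.
#'
#' @param roi a [RoiImage-class].
#' @param k number of clusters (4).
#' @param nSamples number of pixels sampled for fitting (default 10000; all
#'   pixels if the image is smaller).
#' @param seed integer seed.
#' @return A `"TissueLabelMap"` list: `labels` (h x w integer matrix,
#'   1..4 indexing `labelNames`), `centroids` (4 x 3 RGB matrix, rows named
#'   by label), `labelNames`, and `mpp`.
#' @export
classifyTissuePixels <- function(roi, k = 4L, nSamples = 10000L, seed = 1L) {
  px <- imagePixels(roi)
  h <- dim(px)[1]; w <- dim(px)[2]
  flat <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                as.vector(px[, , 3]))
  distinct <- unique(flat)
  if (nrow(distinct) < 2L)
    stop("fewer than k distinct colors")
  if (nrow(distinct) < k) {
    # degenerate palette (e.g. a two-color phantom): the distinct colors
    # are already the exact cluster solution
    centers <- distinct
  } else {
    withr::with_seed(as.integer(seed), {
      idx <- if (nrow(flat) > nSamples) sample.int(nrow(flat), nSamples)
             else seq_len(nrow(flat))
      km <- kmeans(flat[idx, , drop = FALSE], centers = k,
                   algorithm = "Lloyd", nstart = 10L, iter.max = 200L)
    })
    centers <- km$centers
  }
  nc <- nrow(centers)
  # nearest-centroid labelling of every pixel, ties to the lowest index
  d2 <- vapply(seq_len(nc), function(ci)
    rowSums(sweep(flat, 2, centers[ci, ])^2), numeric(nrow(flat)))
  assign <- max.col(-d2, ties.method = "first")

  bright <- rowMeans(centers)
  ord <- order(bright)
  darkest <- ord[1]; brightest <- ord[nc]
  mid <- setdiff(seq_len(nc), c(darkest, brightest))
  satur <- apply(centers, 1, function(rgb) {
    mx <- max(rgb); if (mx <= 0) 0 else (mx - min(rgb)) / mx
  })
  labelOf <- integer(nc)
  labelOf[darkest] <- 1L    # nuclei
  labelOf[brightest] <- 4L  # lumen
  if (length(mid)) {
    stromaIdx <- mid[which.max(satur[mid])]
    labelOf[stromaIdx] <- 3L
    cytoIdx <- setdiff(mid, stromaIdx)
    if (length(cytoIdx)) labelOf[cytoIdx] <- 2L
  }

  labels <- matrix(labelOf[assign], h, w)
  centroids <- centers[order(labelOf), , drop = FALSE]
  rownames(centroids) <- tissueLabelNames[sort(labelOf)]
  structure(list(labels = labels, centroids = centroids,
                 labelNames = tissueLabelNames, mpp = roi@mpp),
            class = "TissueLabelMap")
}

smoothBoundary <- function(b, window = 5L) {
  n <- nrow(b)
  if (window <= 1L || n <= window) return(b)
  half <- (window - 1L) %/% 2L
  idx <- vapply(seq_len(n), function(i)
    ((i - half - 1L):(i + half - 1L)) %% n + 1L, integer(window))
  sm <- cbind(colMeans(matrix(b[idx, 1], window)),
              colMeans(matrix(b[idx, 2], window)))
  sm
}

#' Segment glands from a tissue label map
#'
#' Connected lumen components of at least `minLumenAreaPx` pixels are each
#' grown by morphological dilation until the newly added ring is mostly
#' nuclei-labelled or 5 dilation steps are reached (whichever comes first);
#' the component boundary is extracted, smoothed by a circular moving
#' average over `smoothingWindow` vertices, and its polygon centroid taken
#' as the gland centroid. If no lumen component survives the size filter an
#' empty [GlandSet-class] is returned.
#'
#' @param labelMap result of [classifyTissuePixels()].
#' @param minLumenAreaPx minimum lumen component area in pixels (default 30
#'   at the 4 um/px segmentation scale).
#' @param smoothingWindow boundary moving-average window in vertices.
#' @param roiId id stamped on the result.
#' @return A [GlandSet-class] in the label map's pixel coordinates.
#' @export
segmentGlands <- function(labelMap, minLumenAreaPx = 30, smoothingWindow = 5L,
                          roiId = NA_character_) {
  lab <- labelMap$labels
  lumen <- lab == 4L
  nucl <- lab == 1L
  comp <- EBImage::bwlabel(lumen * 1)
  sizes <- tabulate(comp[comp > 0])
  keepIds <- which(sizes >= minLumenAreaPx)
  bnds <- list(); lum <- numeric(0)
  brush <- EBImage::makeBrush(3, "diamond")
  for (ci in keepIds) {
    cur <- comp == ci
    for (step in 1:5) {
      dil <- EBImage::dilate(cur * 1, brush) > 0
      newpx <- dil & !cur
      cur <- dil
      if (sum(newpx) == 0 || mean(nucl[newpx]) > 0.5) break
    }
    ct <- EBImage::ocontour(cur * 1)
    if (!length(ct)) next
    b <- ct[[which.max(vapply(ct, nrow, integer(1)))]]
    # ocontour returns (dim1, dim2) = (row, col) 0-based; convert to (x, y)
    b <- cbind(b[, 2], b[, 1])
    if (nrow(b) < 3L) next
    b <- smoothBoundary(b, smoothingWindow)
    if (abs(signedPolygonArea(b)) < 1e-9) next
    bnds[[length(bnds) + 1L]] <- b
    lum <- c(lum, sum(comp == ci))
  }
  GlandSet(bnds, mpp = labelMap$mpp, lumenAreas = lum, roiId = roiId)
}

#' Rescale an ROI to a target resolution
#'
#' @param roi a [RoiImage-class].
#' @param targetMpp target microns per pixel.
#' @return A [RoiImage-class] at the target resolution.
#' @export
rescaleRoi <- function(roi, targetMpp) {
  if (abs(roi@mpp - targetMpp) < 1e-9) return(roi)
  px <- imagePixels(roi)
  f <- roi@mpp / targetMpp
  newH <- max(8L, round(dim(px)[1] * f))
  newW <- max(8L, round(dim(px)[2] * f))
  ebi <- EBImage::Image(aperm(px, c(2, 1, 3)) / 255, colormode = "Color")
  ebi <- EBImage::resize(ebi, w = newW, h = newH)
  out <- clamp255(round(aperm(as.array(ebi), c(2, 1, 3)) * 255))
  RoiImage(out, mpp = targetMpp, siteId = roi@siteId,
           patientId = roi@patientId, classLabel = roi@classLabel,
           roiId = roi@roiId)
}

#' Segment an ROI end to end
#'
#' Applies the magnification protocol (rescale to the 4 um/px segmentation
#' scale), pixel classification and lumen-based gland segmentation.
#'
#' @param roi a [RoiImage-class] at any resolution.
#' @param config configuration list, see [defaultConfig()].
#' @param seed integer seed for the pixel-sampling step.
#' @return A [GlandSet-class] at the segmentation scale.
#' @export
segmentRoi <- function(roi, config = defaultConfig(), seed = 1L) {
  roiSeg <- rescaleRoi(roi, config$seg_mpp)
  lm <- classifyTissuePixels(roiSeg, seed = seed)
  segmentGlands(lm, minLumenAreaPx = config$min_lumen_area_px,
                smoothingWindow = config$smoothing_window,
                roiId = roi@roiId)
}
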