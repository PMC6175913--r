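# Assembly of the 242-feature vector: global graph (51), gland shape (100),
# orientation disorder (39), sub-graph (26) and Haralick texture (26).

#' Feature manifest
#'
#' The canonical ordered list of the 242 features with their family tags:
#' 51 global graph, 100 gland shape, 39 orientation disorder, 26 sub-graph
#' and 26 Haralick texture features (216 gland-derived + 26 texture). Tests
#' assert family cardinalities against this manifest.
#'
#' @return data.frame with columns `index`, `name`, `family`.
#' @export
featureManifest <- function() {
  nm <- c(globalGraphFeatureNames(),
          names(shapeFeatures(.unitSquareGlandSet())),
          disorderFeatureNames(),
          subgraphFeatureNames,
          haralickFeatureNames())
  fam <- c(rep("graph", 51L), rep("shape", 100L), rep("disorder", 39L),
           rep("subgraph", 26L), rep("haralick", 26L))
  data.frame(index = seq_along(nm), name = nm, family = fam,
             stringsAsFactors = FALSE)
}

# tiny fixed gland set used only to enumerate shape feature names
.unitSquareGlandSet <- function() {
  b <- cbind(c(0, 12, 12, 0), c(0, 0, 12, 12))
  GlandSet(list(b, b + 40), mpp = 4)
}

withFamily <- function(fam, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", fam, conditionMessage(e)), call. = FALSE))
}

#' Extract the 216 gland-derived features
#'
#' Global graph, shape, disorder and sub-graph families, computed from gland
#' boundaries/centroids alone (no pixel data).
#'
#' @param glands a [GlandSet-class].
#' @param subgraphRadiusUm sub-graph connection radius in microns.
#' @param featMpp feature-extraction scale for shape measurements.
#' @return Named numeric vector of length 216.
#' @export
extractGlandFeatures <- function(glands, subgraphRadiusUm = 200,
                                 featMpp = 16) {
  cen <- centroids(glands, units = "um")
  part <- withFamily("subgraph", buildSubgraphs(cen, subgraphRadiusUm))
  c(withFamily("graph", globalGraphFeatures(cen)),
    withFamily("shape", shapeFeatures(glands, featMpp = featMpp)),
    withFamily("disorder", disorderFeatures(glands, part)),
    withFamily("subgraph", subgraphFeatures(part)))
}

#' Extract the full 242-feature vector for one ROI
#'
#' Concatenates the five family outputs in the fixed manifest order; family
#' errors (e.g. fewer than 4 glands for graph features) propagate with the
#' family named.
#'
#' @param roi a [RoiImage-class].
#' @param glands the matching [GlandSet-class] (ground truth or segmented).
#' @param config configuration list, see [defaultConfig()].
#' @return Named numeric vector of length 242.
#' @export
extractFeatureVector <- function(roi, glands, config = defaultConfig()) {
  v <- c(extractGlandFeatures(glands,
                              subgraphRadiusUm = config$subgraph_radius_um,
                              featMpp = config$feat_mpp),
         withFamily("haralick",
                    haralickFeatures(roi,
                                     windowPx = config$haralick_window_px,
                                     stridePx = config$haralick_stride_px,
                                     grayLevels = config$haralick_gray_levels)))
  stopifnot(identical(names(v), featureManifest()$name))
  v
}
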