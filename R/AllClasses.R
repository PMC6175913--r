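#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats sd var median quantile rnorm runif rbinom wilcox.test
#'   kmeans dist fft prcomp setNames cov
#' @importFrom utils head read.csv write.csv
NULL

#' RoiImage: an RGB region of interest with resolution and provenance
#'
#' Holds an 8-bit RGB image (stored as a numeric `height x width x 3` array
#' with values in `[0, 255]`) together with its microns-per-pixel resolution
#' and provenance metadata (site, patient, class label).
#'
#' @slot pixels numeric array `h x w x 3`, values in `[0, 255]`.
#' @slot mpp microns per pixel (positive scalar).
#' @slot siteId,patientId,classLabel,roiId character scalars (may be `NA`).
#'
#' @export
setClass("RoiImage",
  representation(
    pixels = "array",
    mpp = "numeric",
    siteId = "character",
    patientId = "character",
    classLabel = "character",
    roiId = "character"
  ),
  prototype(
    mpp = 4,
    siteId = NA_character_, patientId = NA_character_,
    classLabel = NA_character_, roiId = NA_character_
  )
)

setValidity("RoiImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a h x w x 3 array")
  if (any(object@pixels < 0) || any(object@pixels > 255))
    return("pixel values must lie in [0, 255]")
  if (length(object@mpp) != 1L || !is.finite(object@mpp) || object@mpp <= 0)
    return("mpp must be a positive scalar")
  TRUE
})

#' Construct a RoiImage
#'
#' @param pixels numeric `h x w x 3` array with values in `[0, 255]`.
#' @param mpp microns per pixel.
#' @param siteId,patientId,classLabel,roiId provenance strings.
#' @return A [RoiImage-class] object.
#' @export
RoiImage <- function(pixels, mpp, siteId = NA_character_,
                     patientId = NA_character_, classLabel = NA_character_,
                     roiId = NA_character_) {
  new("RoiImage", pixels = pixels, mpp = mpp,
      siteId = as.character(siteId), patientId = as.character(patientId),
      classLabel = as.character(classLabel), roiId = as.character(roiId))
}

#' GlandSet: gland boundaries, centroids and lumen areas for one ROI
#'
#' Boundaries and centroids are in pixel coordinates (0-based, x rightward,
#' y downward) at the resolution given by `mpp`; multiply by `mpp` to obtain
#' microns.
#'
#' @slot boundaries list of `n x 2` matrices (columns x, y), one closed
#'   polygon per gland (last vertex connects to the first implicitly).
#' @slot centroids numeric `n x 2` matrix of polygon centroids.
#' @slot areas numeric vector of polygon areas (px^2).
#' @slot lumenAreas numeric vector of lumen component areas (px^2; `NA` when
#'   unknown).
#' @slot mpp microns per pixel of the coordinate system.
#' @slot roiId character source ROI id.
#'
#' @export
setClass("GlandSet",
  representation(
    boundaries = "list",
    centroids = "matrix",
    areas = "numeric",
    lumenAreas = "numeric",
    mpp = "numeric",
    roiId = "character"
  ),
  prototype(mpp = 4, roiId = NA_character_)
)

setValidity("GlandSet", function(object) {
  n <- length(object@boundaries)
  if (n > 0L) {
    if (nrow(object@centroids) != n) return("centroids/boundaries mismatch")
    if (length(object@areas) != n) return("areas/boundaries mismatch")
    if (length(object@lumenAreas) != n)
      return("lumenAreas/boundaries mismatch")
    if (!all(vapply(object@boundaries,
                    function(b) is.matrix(b) && ncol(b) == 2L && nrow(b) >= 3L,
                    logical(1))))
      return("each boundary must be an n x 2 matrix with >= 3 vertices")
    # boundaries pairwise non-identical
    keys <- vapply(object@boundaries,
                   function(b) paste(signif(b, 10), collapse = ","),
                   character(1))
    if (anyDuplicated(keys)) return("gland boundaries must be pairwise distinct")
  }
  if (object@mpp <= 0) return("mpp must be positive")
  TRUE
})

#' Construct a GlandSet
#'
#' @param boundaries list of `n x 2` vertex matrices.
#' @param mpp microns per pixel of the boundary coordinates.
#' @param lumenAreas optional lumen areas (px^2).
#' @param roiId source ROI id.
#' @return A [GlandSet-class] object; centroids and areas are derived from
#'   the polygons.
#' @export
GlandSet <- function(boundaries, mpp, lumenAreas = NULL,
                     roiId = NA_character_) {
  n <- length(boundaries)
  cen <- matrix(numeric(0), 0, 2)
  ar <- numeric(0)
  if (n > 0L) {
    cen <- t(vapply(boundaries, polygonCentroid, numeric(2)))
    ar <- vapply(boundaries, function(b) abs(polygonArea(b)), numeric(1))
  }
  if (is.null(lumenAreas)) lumenAreas <- rep(NA_real_, n)
  new("GlandSet", boundaries = boundaries, centroids = cen, areas = ar,
      lumenAreas = lumenAreas, mpp = mpp, roiId = as.character(roiId))
}

#' FeatureTable: regions-by-features matrix with site/patient/class metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass whose
#' single assay `"features"` holds features in rows and regions in columns;
#' `colData` carries the mandatory `region_id`, `patient_id`, `site` and
#' `class` columns, and `rowData$family` tags each feature with its family.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("region_id", "patient_id", "site", "class")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste0("missing metadata column(s): ", paste(miss, collapse = ", ")))
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix, features in rows, regions in columns (row
#'   and column names required).
#' @param regionInfo data.frame with columns `region_id`, `patient_id`,
#'   `site`, `class` (one row per region, in column order of `values`).
#' @param families optional character vector of per-feature family tags.
#' @param metadata optional list stored in the object metadata (e.g. the
#'   ground-truth annotation of a simulated table).
#' @return A [FeatureTable-class] object.
#' @export
FeatureTable <- function(values, regionInfo, families = NULL,
                         metadata = list()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- regionInfo$region_id
  rd <- S4Vectors::DataFrame(
    family = if (is.null(families)) rep(NA_character_, nrow(values)) else families
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values),
    colData = S4Vectors::DataFrame(regionInfo),
    rowData = rd,
    metadata = metadata
  )
  new("FeatureTable", se)
}

#' StainModel: hematoxylin/eosin stain vectors plus reference histograms
#'
#' @slot vectors 3 x 2 matrix of unit stain vectors in optical-density
#'   space; column 1 hematoxylin, column 2 eosin.
#' @slot refQuantiles list of two numeric vectors: the 256 reference
#'   quantiles of each stain's concentration over the template's pixels
#'   assigned to that stain.
#' @slot odThreshold background optical-density threshold.
#'
#' @export
setClass("StainModel",
  representation(vectors = "matrix", refQuantiles = "list",
                 odThreshold = "numeric"),
  prototype(odThreshold = 0.15)
)

setValidity("StainModel", function(object) {
  v <- object@vectors
  if (!all(dim(v) == c(3, 2))) return("vectors must be 3 x 2")
  if (any(abs(sqrt(colSums(v^2)) - 1) > 1e-6))
    return("stain vectors must be unit norm")
  cosang <- abs(sum(v[, 1] * v[, 2]))
  if (cosang > 1 - 1e-8) return("stain vectors must be non-collinear")
  TRUE
})

#' InstabilityProfile: per-feature preparation-induced instability (PI)
#'
#' @slot pi named numeric vector of PI values in `[0, 1]`.
#' @slot protocol list describing how PI was computed (mode, alpha,
#'   repetitions, subsample size, seed).
#' @slot sites character vector of site ids used.
#'
#' @export
setClass("InstabilityProfile",
  representation(pi = "numeric", protocol = "list", sites = "character"))

setValidity("InstabilityProfile", function(object) {
  if (any(object@pi < 0 | object@pi > 1, na.rm = TRUE))
    return("PI values must lie in [0, 1]")
  if (identical(object@protocol$mode, "exact")) {
    m <- length(object@sites)
    np <- choose(m, 2)
    bad <- abs(object@pi * np - round(object@pi * np)) > 1e-9
    if (any(bad, na.rm = TRUE))
      return("exact-mode PI values must be multiples of 1/C(m,2)")
  }
  TRUE
})

#' SelectionResult: an ordered selected feature set
#'
#' @slot features character vector of selected feature names (ordered).
#' @slot scores named numeric vector of per-feature selection scores.
#' @slot theta selector id, one of `"SFS"`, `"WLCX"`, `"mRMR"`, `"ROC"`.
#' @slot gated logical; `TRUE` for stability-gated selection (FS_sd).
#' @slot piThreshold PI threshold used when gated (`NA` otherwise).
#' @slot seed integer seed used.
#'
#' @export
setClass("SelectionResult",
  representation(features = "character", scores = "numeric",
                 theta = "character", gated = "logical",
                 piThreshold = "numeric", seed = "numeric"))

setValidity("SelectionResult", function(object) {
  if (anyDuplicated(object@features)) return("selected features must be distinct")
  if (!object@theta %in% c("SFS", "WLCX", "mRMR", "ROC"))
    return("unknown selector id")
  TRUE
})

#' EvaluationReport: hold-one-site-out results
#'
#' @slot task task id, `"cancer"` or `"gleason"`.
#' @slot records data.frame with one row per (fold, selector, classifier,
#'   gated) combination: columns `site_heldout`, `theta`, `kappa`, `gated`,
#'   `auc`, `n_test`, `features`.
#' @slot seed integer seed.
#' @slot config list snapshot of the configuration used.
#'
#' @export
setClass("EvaluationReport",
  representation(task = "character", records = "data.frame",
                 seed = "numeric", config = "list"))

setMethod("show", "RoiImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RoiImage %d x %d px @ %.3g um/px  [site=%s patient=%s class=%s]\n",
              d[1], d[2], object@mpp, object@siteId, object@patientId,
              object@classLabel))
})

setMethod("show", "GlandSet", function(object) {
  cat(sprintf("GlandSet with %d gland(s) @ %.3g um/px (roi=%s)\n",
              length(object@boundaries), object@mpp, object@roiId))
})

setMethod("show", "StainModel", function(object) {
  cat("StainModel (OD threshold", object@odThreshold, ")\n")
  cat("  H:", paste(sprintf("%.3f", object@vectors[, 1]), collapse = " "), "\n")
  cat("  E:", paste(sprintf("%.3f", object@vectors[, 2]), collapse = " "), "\n")
})

setMethod("show", "InstabilityProfile", function(object) {
  cat(sprintf("InstabilityProfile: %d feature(s), %d site(s), mode=%s, alpha=%g\n",
              length(object@pi), length(object@sites),
              object@protocol$mode, object@protocol$alpha))
  print(summary(object@pi))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult theta=%s gated=%s%s\n", object@theta,
              object@gated,
              if (isTRUE(object@gated)) sprintf(" (PI < %g)", object@piThreshold)
              else ""))
  cat("  ", paste(object@features, collapse = ", "), "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport task=%s: %d record(s), %d fold site(s)\n",
              object@task, nrow(object@records),
              length(unique(object@records$site_heldout))))
})
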