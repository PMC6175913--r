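#' Accessors for glandstab classes
#'
#' Accessor generics for the core data objects: pixel array and resolution of
#' a [RoiImage-class]; boundaries/centroids of a [GlandSet-class]; values and
#' region metadata of a [FeatureTable-class]; PI values of an
#' [InstabilityProfile-class]; selected features of a
#' [SelectionResult-class]; records of an [EvaluationReport-class].
#'
#' @param x an object.
#' @param units for `centroids`/`boundaries`: `"px"` (native pixels) or
#'   `"um"` (microns).
#' @return The accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))
#' @rdname accessors
#' @export
setMethod("imagePixels", "RoiImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("micronsPerPixel", function(x) standardGeneric("micronsPerPixel"))
#' @rdname accessors
#' @export
setMethod("micronsPerPixel", "RoiImage", function(x) x@mpp)
#' @rdname accessors
#' @export
setMethod("micronsPerPixel", "GlandSet", function(x) x@mpp)

#' @rdname accessors
#' @export
setGeneric("glandCount", function(x) standardGeneric("glandCount"))
#' @rdname accessors
#' @export
setMethod("glandCount", "GlandSet", function(x) length(x@boundaries))

#' @rdname accessors
#' @export
setGeneric("boundaries", function(x, units = "px") standardGeneric("boundaries"))
#' @rdname accessors
#' @export
setMethod("boundaries", "GlandSet", function(x, units = "px") {
  units <- match.arg(units, c("px", "um"))
  if (units == "px") return(x@boundaries)
  lapply(x@boundaries, function(b) b * x@mpp)
})

#' @rdname accessors
#' @export
setGeneric("centroids", function(x, units = "px") standardGeneric("centroids"))
#' @rdname accessors
#' @export
setMethod("centroids", "GlandSet", function(x, units = "px") {
  units <- match.arg(units, c("px", "um"))
  if (units == "px") return(x@centroids)
  x@centroids * x@mpp
})

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureTable", function(x)
  SummarizedExperiment::assay(x, "features"))

#' @rdname accessors
#' @export
setGeneric("regionInfo", function(x) standardGeneric("regionInfo"))
#' @rdname accessors
#' @export
setMethod("regionInfo", "FeatureTable", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname accessors
#' @export
setGeneric("featureFamilies", function(x) standardGeneric("featureFamilies"))
#' @rdname accessors
#' @export
setMethod("featureFamilies", "FeatureTable", function(x)
  setNames(SummarizedExperiment::rowData(x)$family, rownames(x)))

#' @rdname accessors
#' @export
setGeneric("piValues", function(x) standardGeneric("piValues"))
#' @rdname accessors
#' @export
setMethod("piValues", "InstabilityProfile", function(x) x@pi)

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("reportRecords", function(x) standardGeneric("reportRecords"))
#' @rdname accessors
#' @export
setMethod("reportRecords", "EvaluationReport", function(x) x@records)
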