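# Readers and writers: feature-table CSV (regions in rows: region_id,
# patient_id, site, class, then feature columns), the GlandSet JSON sidecar
# (shared by ground truth and segmentation output), and PNG images.

#' Read a feature table from CSV
#'
#' The CSV must have a header with the metadata columns `region_id`,
#' `patient_id`, `site`, `class` followed by numeric feature columns. Lines
#' starting with `#` (embedded config snapshots) are skipped. Missing
#' metadata columns and non-numeric feature cells are reported by name and
#' position.
#'
#' @param path CSV file path.
#' @return A [FeatureTable-class]; row order is preserved.
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 colClasses = "character", check.names = FALSE)
  need <- c("region_id", "patient_id", "site", "class")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing metadata column(s): ", paste(miss, collapse = ", "))
  featCols <- setdiff(colnames(df), need)
  vals <- matrix(NA_real_, length(featCols), nrow(df),
                 dimnames = list(featCols, df$region_id))
  for (fc in featCols) {
    v <- suppressWarnings(as.numeric(df[[fc]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric feature value '%s' at row %d, column '%s'",
                   df[[fc]][bad[1]], bad[1], fc))
    vals[fc, ] <- v
  }
  FeatureTable(vals, df[, need])
}

#' Write a feature table to CSV
#'
#' @param table a [FeatureTable-class].
#' @param path output path.
#' @param config optional configuration list; when given, its snapshot is
#'   embedded as leading `#` comment lines.
#' @return The path, invisibly.
#' @export
writeFeatureTable <- function(table, path, config = NULL) {
  info <- regionInfo(table)[, c("region_id", "patient_id", "site", "class")]
  df <- cbind(info, as.data.frame(t(featureValues(table)),
                                  check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(configSnapshotLines(config), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write / read a GlandSet sidecar file
#'
#' A JSON text schema shared by the synthetic ground truth and the
#' segmentation output, so the two are interchangeable downstream: polygons
#' are ordered `(x, y)` pixel vertex lists, 0-based, x rightward, y
#' downward.
#'
#' @param glands a [GlandSet-class].
#' @param path file path (JSON).
#' @return `readGlandSet` returns the [GlandSet-class].
#' @export
writeGlandSet <- function(glands, path) {
  obj <- list(
    roi_id = glands@roiId,
    microns_per_pixel = glands@mpp,
    glands = lapply(seq_len(glandCount(glands)), function(i)
      list(boundary = unname(glands@boundaries[[i]]),
           centroid = unname(glands@centroids[i, ]),
           area_px = glands@areas[i],
           lumen_area_px = glands@lumenAreas[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGlandSet
#' @export
readGlandSet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(x$glands)) {
    bnds <- lapply(x$glands$boundary, function(b) as.matrix(b))
    lum <- as.numeric(x$glands$lumen_area_px)
  } else {
    bnds <- lapply(x$glands, function(g) as.matrix(g$boundary))
    lum <- vapply(x$glands, function(g) as.numeric(g$lumen_area_px),
                  numeric(1))
  }
  GlandSet(bnds, mpp = x$microns_per_pixel, lumenAreas = lum,
           roiId = x$roi_id)
}

#' Write / read an ROI image as 8-bit PNG
#'
#' @param roi a [RoiImage-class].
#' @param path PNG path.
#' @param mpp,siteId,patientId,classLabel,roiId metadata attached on read
#'   (PNG carries no resolution metadata).
#' @return `readRoiPng` returns the [RoiImage-class].
#' @export
writeRoiPng <- function(roi, path) {
  png::writePNG(imagePixels(roi) / 255, path)
  invisible(path)
}

#' @rdname writeRoiPng
#' @export
readRoiPng <- function(path, mpp, siteId = NA, patientId = NA,
                       classLabel = NA, roiId = NA) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  RoiImage(round(a * 255), mpp = mpp, siteId = siteId,
           patientId = patientId, classLabel = classLabel, roiId = roiId)
}
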