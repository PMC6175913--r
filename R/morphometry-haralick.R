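# Haralick texture family: the ROI is converted to grayscale (luminosity
# weights), quantized, and a symmetric unit-offset co-occurrence matrix
# (averaged over 4 directions) is computed in sliding windows; the 13
# co-occurrence statistics are aggregated across windows by mean and std.

haralickFeatureNames <- function() {
  as.vector(vapply(glcmStatNames, function(s)
    paste0("haralick_", c("mean", "std"), "_", s), character(2)))
}

#' Haralick texture features (26 values)
#'
#' @param roi a [RoiImage-class].
#' @param windowPx sliding-window side in pixels (default 64); images
#'   smaller than one window are processed as a single window.
#' @param stridePx window stride in pixels (default `windowPx / 2`).
#' @param grayLevels number of gray levels after quantization (default 64).
#' @return Named numeric vector of length 26 (mean and std of each of the 13
#'   co-occurrence statistics across windows).
#' @export
haralickFeatures <- function(roi, windowPx = 64L, stridePx = windowPx %/% 2L,
                             grayLevels = 64L) {
  px <- imagePixels(roi)
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  G <- as.integer(grayLevels)
  q <- pmin(floor(gray * G / 256) + 1L, G)
  storage.mode(q) <- "integer"
  nr <- nrow(q); nc <- ncol(q)
  w <- min(windowPx, nr, nc)
  rows <- unique(c(seq(1L, max(1L, nr - w + 1L), by = stridePx)))
  cols <- unique(c(seq(1L, max(1L, nc - w + 1L), by = stridePx)))
  S <- NULL
  for (r0 in rows) for (c0 in cols) {
    win <- q[r0:(r0 + w - 1L), c0:(c0 + w - 1L), drop = FALSE]
    S <- rbind(S, cooccurrenceStats(grayCooccurrence(win, G)))
  }
  out <- numeric(0)
  for (s in glcmStatNames) {
    v <- S[, s]
    out <- c(out, mean(v), if (length(v) > 1L) sd(v) else 0)
  }
  setNames(out, haralickFeatureNames())
}
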