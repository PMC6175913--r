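# Macenko-style stain normalization. Optical density is computed per channel
# as -log10((I + 1)/256); background pixels (every channel below the OD
# threshold) are excluded from estimation and pass through normalization
# unmodified. Stain vectors are the 1st/99th percentile angles in the
# dominant OD plane found by SVD; per-stain intensity histograms are matched
# to a template by 256-bin quantile mapping.

odFromRGB <- function(px) -log10((px + 1) / 256)
rgbFromOD <- function(od) clamp255(256 * 10^(-od) - 1)

tissueMaskOD <- function(od, beta) {
  od[, , 1] >= beta | od[, , 2] >= beta | od[, , 3] >= beta
}

#' Estimate a stain model from an H&E image
#'
#' Background pixels (optical density below `beta` in every channel) are
#' removed; the two dominant OD directions are found by singular value
#' decomposition; each tissue pixel's angle in that plane is computed and
#' the stain vectors are placed at the `anglePercentiles` of those angles.
#' Vectors are labelled hematoxylin/eosin by proximity to the canonical
#' hematoxylin direction, and the per-stain reference intensity quantiles of
#' this image are recorded for histogram matching.
#'
#' @param roi a [RoiImage-class].
#' @param beta background OD threshold (default 0.15).
#' @param anglePercentiles two percentiles of the angle distribution
#'   (default `c(1, 99)`); equal percentiles give collinear vectors and are
#'   rejected.
#' @return A [StainModel-class].
#' @export
estimateStainModel <- function(roi, beta = 0.15, anglePercentiles = c(1, 99)) {
  od <- odFromRGB(imagePixels(roi))
  mask <- tissueMaskOD(od, beta)
  if (sum(mask) < 100)
    stop("insufficient tissue for stain estimation")
  M <- cbind(od[, , 1][mask], od[, , 2][mask], od[, , 3][mask])
  sv <- svd(M, nu = 0, nv = 2)
  V <- sv$v
  # orient the plane so most projections are positive
  for (j in 1:2) if (median(M %*% V[, j]) < 0) V[, j] <- -V[, j]
  proj <- M %*% V
  ang <- atan2(proj[, 2], proj[, 1])
  qa <- quantile(ang, anglePercentiles / 100, names = FALSE)
  mkvec <- function(a) {
    v <- V[, 1] * cos(a) + V[, 2] * sin(a)
    if (sum(v) < 0) v <- -v
    v / sqrt(sum(v^2))
  }
  v1 <- mkvec(qa[1]); v2 <- mkvec(qa[2])
  if (abs(sum(v1 * v2)) > 1 - 1e-8)
    stop("degenerate angle percentiles: stain vectors are collinear")
  hRef <- c(0.65, 0.70, 0.29); hRef <- hRef / sqrt(sum(hRef^2))
  if (sum(v1 * hRef) >= sum(v2 * hRef)) {
    vecs <- cbind(H = v1, E = v2)
  } else {
    vecs <- cbind(H = v2, E = v1)
  }
  conc <- stainConcentrations(od, vecs, mask)
  refs <- lapply(1:2, function(s) {
    vals <- conc$C[conc$assign == s, s]
    if (!length(vals)) vals <- 0
    quantile(vals, probs = seq(0, 1, length.out = 256), names = FALSE)
  })
  new("StainModel", vectors = vecs, refQuantiles = refs, odThreshold = beta)
}

# least-squares color deconvolution: concentrations C (n x 2) of the tissue
# pixels against the stain matrix, plus per-pixel dominant-stain assignment
stainConcentrations <- function(od, vecs, mask) {
  M <- cbind(od[, , 1][mask], od[, , 2][mask], od[, , 3][mask])
  Cmat <- t(solve(crossprod(vecs), crossprod(vecs, t(M))))
  Cmat[Cmat < 0] <- 0
  assign <- ifelse(Cmat[, 1] >= Cmat[, 2], 1L, 2L)
  list(C = Cmat, assign = assign)
}

# monotone quantile mapping of values onto reference quantiles
quantileMap <- function(x, refQ) {
  if (!length(x)) return(x)
  srcQ <- quantile(x, probs = seq(0, 1, length.out = 256), names = FALSE)
  stats::approx(x = srcQ, y = refQ, xout = x, rule = 2, ties = "ordered")$y
}

#' Normalize an image to a template stain model
#'
#' The image is deconvolved against its own stain vectors; each tissue pixel
#' is assigned to the stain with the higher intensity; each stain's
#' intensity histogram (over its assigned pixels) defines a 256-bin quantile
#' mapping onto the template's reference histogram, applied to that stain
#' channel of all tissue pixels; the image is recomposed through the
#' template's stain vectors. Background pixels pass through unmodified.
#'
#' @param roi a [RoiImage-class].
#' @param model [StainModel-class] of this image (from
#'   [estimateStainModel()] on `roi`).
#' @param template [StainModel-class] of the template image.
#' @return A normalized [RoiImage-class] of the same dimensions.
#' @export
normalizeImage <- function(roi, model, template) {
  px <- imagePixels(roi)
  od <- odFromRGB(px)
  beta <- model@odThreshold
  mask <- tissueMaskOD(od, beta)
  if (!any(mask)) return(roi)
  dec <- stainConcentrations(od, model@vectors, mask)
  Cmat <- dec$C
  for (s in 1:2) {
    sel <- dec$assign == s
    if (!any(sel)) next
    m <- quantileMap(Cmat[sel, s], template@refQuantiles[[s]])
    # scale both channels of the pixel by the dominant channel's mapping
    # ratio so relative stain mixture is preserved
    ratio <- ifelse(Cmat[sel, s] > 1e-8, m / Cmat[sel, s], 1)
    Cmat[sel, ] <- Cmat[sel, ] * ratio
  }
  odNew <- Cmat %*% t(template@vectors)
  out <- px
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[mask] <- rgbFromOD(odNew[, ch])
    out[, , ch] <- plane
  }
  RoiImage(round(clamp255(out)), mpp = roi@mpp, siteId = roi@siteId,
           patientId = roi@patientId, classLabel = roi@classLabel,
           roiId = roi@roiId)
}

#' Write / read a stain model as a small text file
#'
#' @param model a [StainModel-class].
#' @param path file path (YAML).
#' @return `readStainModel` returns the [StainModel-class].
#' @export
writeStainModel <- function(model, path) {
  yaml::write_yaml(list(vectors = as.numeric(model@vectors),
                        refH = model@refQuantiles[[1]],
                        refE = model@refQuantiles[[2]],
                        od_threshold = model@odThreshold), path)
  invisible(path)
}

#' @rdname writeStainModel
#' @export
readStainModel <- function(path) {
  x <- yaml::read_yaml(path)
  new("StainModel",
      vectors = matrix(as.numeric(x$vectors), 3, 2,
                       dimnames = list(NULL, c("H", "E"))),
      refQuantiles = list(as.numeric(x$refH), as.numeric(x$refE)),
      odThreshold = x$od_threshold)
}
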