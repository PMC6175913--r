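# Gland shape family: 25 boundary measurements per gland, aggregated across
# glands by mean, median, standard deviation and min/max ratio (100 features).

shapeMeasurementNames <- c(
  "area", "perimeter", "area_ratio", "perimeter_ratio", "distance_ratio",
  "std_of_distance", "variance_of_distance", "smoothness",
  "fractal_dimension",
  paste0("invariant_moment_", 1:7),
  paste0("fourier_descriptor_", 1:9)
)

shapeAggNames <- c("mean", "median", "std", "minmax")

#' Orientation of a gland boundary
#'
#' The angle, in degrees in `[0, 180)`, between the first principal axis of
#' the boundary vertex cloud and the reference direction (1, 0). When the
#' two principal axes are tied (e.g. a circle) the documented tie-break
#' returns the lower angle, 0.
#'
#' @param boundary `n x 2` matrix of boundary vertices (`n >= 3`).
#' @return Angle in degrees in `[0, 180)`.
#' @export
glandOrientation <- function(boundary) {
  if (nrow(boundary) < 3L) stop("boundary needs at least 3 points")
  cv <- cov(boundary)
  ev <- eigen(cv, symmetric = TRUE)
  l1 <- ev$values[1]; l2 <- ev$values[2]
  if (l1 <= 1e-300 || l2 / l1 < 1e-12)
    stop("degenerate boundary: points are collinear")
  if ((l1 - l2) / l1 < 1e-9) return(0)  # isotropic: axes tied
  v <- ev$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  ang %% 180
}

# Per-gland 25-measurement matrix. Boundaries are taken in microns and
# converted to the 16 um/px feature-extraction scale, so areas/lengths are in
# 1.25X-equivalent pixel units.
shapeMeasurements <- function(glands, featMpp = 16) {
  bnds <- boundaries(glands, units = "um")
  meas <- t(vapply(bnds, function(bu) {
    b <- bu / featMpp
    ctr <- polygonCentroid(b)
    d <- sqrt(rowSums(sweep(b, 2, ctr)^2))
    nb <- length(d)
    neighAvg <- (d[c(nb, seq_len(nb - 1L))] + d[c(seq_len(nb)[-1], 1L)]) / 2
    area <- polygonArea(b)
    perim <- polygonPerimeter(b)
    mec <- minEnclosingCircle(b)
    areaRatio <- if (mec$r > 0) area / (pi * mec$r^2) else 1
    perimRatio <- convexHullPerimeter(b) / perim
    hu <- huMoments(b)
    # Fourier descriptors: magnitudes at frequencies 2..10 of the arc-length
    # resampled complex boundary, normalized by the fundamental (freq 1)
    rs <- resampleBoundary(b, 128L)
    z <- complex(real = rs[, 1], imaginary = rs[, 2])
    Fz <- fft(z)
    fund <- Mod(Fz[2])
    fd <- if (fund > 1e-12) Mod(Fz[3:11]) / fund else rep(0, 9)
    c(area, perim, areaRatio, perimRatio,
      mean(d) / max(d), sd(d), var(d),
      mean(abs(d - neighAvg)),
      boxCountDimension(b),
      hu, fd)
  }, numeric(25L)))
  colnames(meas) <- shapeMeasurementNames
  meas
}

aggregateShape <- function(v) {
  c(mean = mean(v), median = median(v),
    std = if (length(v) > 1L) sd(v) else 0,
    minmax = minMaxRatio(v))
}

#' Gland shape features (100 values)
#'
#' For every gland, 25 boundary measurements are computed (area, perimeter,
#' area ratio to the minimum enclosing circle, convex-hull perimeter ratio,
#' centroid-boundary distance statistics, smoothness, box-counting fractal
#' dimension, the 7 Hu invariant moments and 9 Fourier descriptors); each is
#' aggregated across glands by mean, median, standard deviation and min/max
#' ratio. A single-gland ROI gives std 0 and min/max ratio 1.
#'
#' @param glands a [GlandSet-class] with at least one gland.
#' @param featMpp microns per pixel of the feature-extraction scale
#'   (default 16, i.e. 1.25X-equivalent).
#' @return Named numeric vector of length 100.
#' @export
shapeFeatures <- function(glands, featMpp = 16) {
  if (glandCount(glands) < 1L) stop("shape features need at least one gland")
  meas <- shapeMeasurements(glands, featMpp = featMpp)
  out <- numeric(0)
  for (m in shapeMeasurementNames) {
    a <- aggregateShape(meas[, m])
    names(a) <- paste0("shape_", shapeAggNames, "_", m)
    out <- c(out, a)
  }
  out
}
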