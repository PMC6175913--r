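# Synthetic H&E-like ROI generator: lumen-bearing glands (near-white lumen
# inside a dark epithelial annulus) on textured pink stroma, with per-class
# density/size/arrangement presets and configurable site effects. The
# renderer is deliberately simple -- the downstream segmentation keys on
# lumen brightness, not on photorealism.

.stromaRGB <- c(228, 160, 195)
.nucleiRGB <- c(105, 70, 150)
.lumenRGB <- c(248, 246, 250)
.cytoplasmRGB <- c(190, 150, 200)

roiClassDefaults <- function(classLabel) {
  switch(classLabel,
    noncancer = list(nGlands = 25L, glandRadiusMeanUm = 55, crowding = 1,
                     lumenFraction = 1),
    cancer = list(nGlands = 45L, glandRadiusMeanUm = 35, crowding = 1.6,
                  lumenFraction = 0.9),
    gleason3 = list(nGlands = 45L, glandRadiusMeanUm = 35, crowding = 1.6,
                    lumenFraction = 0.95),
    gleason4 = list(nGlands = 55L, glandRadiusMeanUm = 30, crowding = 2.2,
                    lumenFraction = 0.4),
    stop("unknown class label: ", classLabel)
  )
}

# vectorized even-odd point-in-polygon over grid coordinates
pipMask <- function(poly, px, py) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    dy <- poly[j, 2] - poly[i, 2]
    cond <- ((poly[i, 2] > py) != (poly[j, 2] > py)) &
      (px < (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
         ifelse(dy == 0, 1e-300, dy) + poly[i, 1])
    inside <- xor(inside, cond)
    j <- i
  }
  inside
}

# radial irregularity profile of a gland boundary: a smooth perturbation of
# the unit circle (glands are wavy, not perfect ellipses)
glandRadialProfile <- function(t, wob) {
  1 + wob[1] * sin(3 * t + wob[3]) + wob[2] * sin(5 * t + wob[4])
}

glandPolygon <- function(cx, cy, a, b, phi, wob, nVert = 48L) {
  t <- seq(0, 2 * pi, length.out = nVert + 1L)[-(nVert + 1L)]
  r <- glandRadialProfile(t, wob)
  cbind(cx + a * r * cos(t) * cos(phi) - b * r * sin(t) * sin(phi),
        cy + a * r * cos(t) * sin(phi) + b * r * sin(t) * cos(phi))
}

#' Simulate an H&E-like region of interest with ground-truth glands
#'
#' Renders `nGlands` elliptical glands (a dark nuclear annulus around a
#' near-white lumen, or a lumenless pale fill for the fraction
#' `1 - lumenFraction`, emulating fused Gleason-4 glands) on textured pink
#' stroma. Gland placement respects a crowding-controlled minimum centroid
#' spacing; the generator is a pure function of its parameters and seed.
#'
#' @param classLabel one of `"noncancer"`, `"cancer"`, `"gleason3"`,
#'   `"gleason4"`; sets the per-class defaults for the `NULL` arguments.
#' @param imageSize integer `(height, width)` in pixels.
#' @param mpp microns per pixel of the rendered image (default 4, i.e. a 5X
#'   equivalent).
#' @param nGlands number of glands.
#' @param glandRadiusMeanUm,glandRadiusCv mean and coefficient of variation
#'   of the gland semi-major axis, microns.
#' @param crowding crowding factor `>= 0`; higher packs centroids closer.
#' @param lumenFraction fraction of glands rendered with a visible lumen.
#' @param siteId,patientId,roiId provenance strings.
#' @param seed integer seed (required for reproducibility).
#' @return A list with `roi` (a [RoiImage-class]) and `glands` (the
#'   ground-truth [GlandSet-class]).
#' @export
simulateRoi <- function(classLabel = "noncancer", imageSize = c(384L, 384L),
                        mpp = 4, nGlands = NULL, glandRadiusMeanUm = NULL,
                        glandRadiusCv = 0.25, crowding = NULL,
                        lumenFraction = NULL, siteId = NA, patientId = NA,
                        roiId = NA, seed = 1L) {
  defs <- roiClassDefaults(classLabel)
  if (is.null(nGlands)) nGlands <- defs$nGlands
  if (is.null(glandRadiusMeanUm)) glandRadiusMeanUm <- defs$glandRadiusMeanUm
  if (is.null(crowding)) crowding <- defs$crowding
  if (is.null(lumenFraction)) lumenFraction <- defs$lumenFraction
  stopifnot(nGlands >= 1L, glandRadiusMeanUm > 0, crowding >= 0,
            lumenFraction > 0, lumenFraction <= 1)
  h <- imageSize[1]; w <- imageSize[2]

  withr::with_seed(as.integer(seed), {
    # gland geometry in pixels
    aPx <- pmax(3, rnorm(nGlands, glandRadiusMeanUm,
                         glandRadiusCv * glandRadiusMeanUm) / mpp)
    bPx <- aPx * runif(nGlands, 0.55, 0.95)
    phi <- runif(nGlands, 0, pi)
    # per-gland boundary irregularity (amplitudes and phases)
    wobs <- cbind(runif(nGlands, 0.02, 0.08), runif(nGlands, 0.01, 0.05),
                  runif(nGlands, 0, 2 * pi), runif(nGlands, 0, 2 * pi))
    minSpace <- outer(aPx, aPx, "+") * 1.25 / max(crowding, 0.05)

    centers <- matrix(NA_real_, nGlands, 2)
    placed <- 0L
    tries <- 0L
    maxTries <- 400L * nGlands
    while (placed < nGlands && tries < maxTries) {
      tries <- tries + 1L
      i <- placed + 1L
      m <- aPx[i] * 1.15 + 2
      if (w - 1 - m <= m || h - 1 - m <= m) break
      cand <- c(runif(1, m, w - 1 - m), runif(1, m, h - 1 - m))
      ok <- TRUE
      if (placed > 0L) {
        dd <- sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                 2, cand)^2))
        ok <- all(dd >= minSpace[i, seq_len(placed)])
      }
      if (ok) {
        centers[i, ] <- cand
        placed <- placed + 1L
      }
    }
    if (placed < nGlands)
      stop(sprintf(paste0("could not place %d glands in a %dx%d image ",
                          "(radius %.0f um, crowding %.2f): infeasible ",
                          "parameters"),
                   nGlands, h, w, glandRadiusMeanUm, crowding))

    nLumen <- round(lumenFraction * nGlands)
    hasLumen <- rep(FALSE, nGlands)
    if (nLumen > 0L) hasLumen[sample.int(nGlands, nLumen)] <- TRUE

    # stroma background with texture noise
    px <- array(0, c(h, w, 3))
    for (ch in 1:3)
      px[, , ch] <- clamp255(.stromaRGB[ch] + rnorm(h * w, 0, 8))

    bndList <- vector("list", nGlands)
    lumenAreas <- numeric(nGlands)
    colIdx <- matrix(rep(0:(w - 1), each = h), h, w)  # x coordinate
    rowIdx <- matrix(rep(0:(h - 1), w), h, w)         # y coordinate
    for (i in seq_len(nGlands)) {
      poly <- glandPolygon(centers[i, 1], centers[i, 2], aPx[i], bPx[i],
                           phi[i], wobs[i, ])
      bndList[[i]] <- poly
      margin <- aPx[i] * 1.15 + 1
      x0 <- max(0, floor(centers[i, 1] - margin))
      x1 <- min(w - 1, ceiling(centers[i, 1] + margin))
      y0 <- max(0, floor(centers[i, 2] - margin))
      y1 <- min(h - 1, ceiling(centers[i, 2] + margin))
      rows <- (y0:y1) + 1L; cols <- (x0:x1) + 1L
      xs <- colIdx[rows, cols]; ys <- rowIdx[rows, cols]
      dx <- xs - centers[i, 1]; dy <- ys - centers[i, 2]
      u <- (dx * cos(phi[i]) + dy * sin(phi[i])) / aPx[i]
      v <- (-dx * sin(phi[i]) + dy * cos(phi[i])) / bPx[i]
      rr <- sqrt(u^2 + v^2) /
        glandRadialProfile(atan2(v, u), wobs[i, ])
      outer <- rr <= 1
      inner <- rr <= 0.62
      innerRGB <- if (hasLumen[i]) .lumenRGB else .cytoplasmRGB
      innerNoise <- if (hasLumen[i]) 2 else 6
      for (ch in 1:3) {
        blk <- px[rows, cols, ch]
        ring <- outer & !inner
        blk[ring] <- clamp255(.nucleiRGB[ch] + rnorm(sum(ring), 0, 10))
        blk[inner] <- clamp255(innerRGB[ch] + rnorm(sum(inner), 0, innerNoise))
        px[rows, cols, ch] <- blk
      }
      lumenAreas[i] <- if (hasLumen[i]) sum(inner) else 0
    }
    px <- round(px)
  })

  roi <- RoiImage(px, mpp = mpp, siteId = siteId, patientId = patientId,
                  classLabel = classLabel, roiId = roiId)
  glands <- GlandSet(bndList, mpp = mpp, lumenAreas = lumenAreas,
                     roiId = as.character(roiId))
  list(roi = roi, glands = glands)
}

#' Describe a site effect
#'
#' A site effect bundles the preparation/scanning appearance differences the
#' synthetic module emulates: an additive RGB shift, a contrast scaling
#' about mid-gray, Gaussian blur, a rotation of the optical-density plane
#' spanned by the canonical hematoxylin/eosin directions, and a gland
#' dropout rate. The identity effect leaves an image bit-identical.
#'
#' @param siteId site label.
#' @param rgbShift numeric length-3 additive shift (intensity units).
#' @param contrastScale positive scale about 128.
#' @param blurSigmaPx Gaussian blur sigma in pixels (`>= 0`).
#' @param stainRotationDeg rotation in the OD stain plane, degrees.
#' @param glandDropoutRate per-gland dropout probability in `[0, 1)`.
#' @return A validated `"SiteEffect"` list.
#' @export
siteEffect <- function(siteId, rgbShift = c(0, 0, 0), contrastScale = 1,
                       blurSigmaPx = 0, stainRotationDeg = 0,
                       glandDropoutRate = 0) {
  stopifnot(length(rgbShift) == 3L, contrastScale > 0, blurSigmaPx >= 0,
            glandDropoutRate >= 0, glandDropoutRate < 1)
  structure(list(siteId = as.character(siteId), rgbShift = rgbShift,
                 contrastScale = contrastScale, blurSigmaPx = blurSigmaPx,
                 stainRotationDeg = stainRotationDeg,
                 glandDropoutRate = glandDropoutRate),
            class = "SiteEffect")
}

isIdentityEffect <- function(e) {
  all(e$rgbShift == 0) && e$contrastScale == 1 && e$blurSigmaPx == 0 &&
    e$stainRotationDeg == 0 && e$glandDropoutRate == 0
}

# canonical H&E OD-plane basis (orthonormalized)
.stainBasis <- function() {
  h <- c(0.65, 0.70, 0.29); h <- h / sqrt(sum(h^2))
  e <- c(0.07, 0.99, 0.11); e <- e - sum(e * h) * h; e <- e / sqrt(sum(e^2))
  cbind(h, e)
}

#' Drop glands from a rendered ROI
#'
#' Each gland is removed independently with probability `rate`; removed
#' glands are painted over with stroma texture. Returns both the modified
#' image and the surviving ground-truth gland set.
#'
#' @param roi a [RoiImage-class].
#' @param glands the matching [GlandSet-class].
#' @param rate per-gland dropout probability.
#' @param seed integer seed.
#' @return list with `roi` and `glands`.
#' @export
dropGlands <- function(roi, glands, rate, seed = 1L) {
  n <- glandCount(glands)
  px <- imagePixels(roi)
  withr::with_seed(as.integer(seed), {
    drop <- which(runif(n) < rate)
    if (length(drop)) {
      h <- dim(px)[1]; w <- dim(px)[2]
      for (i in drop) {
        poly <- glands@boundaries[[i]]
        x0 <- max(0, floor(min(poly[, 1])) - 1)
        x1 <- min(w - 1, ceiling(max(poly[, 1])) + 1)
        y0 <- max(0, floor(min(poly[, 2])) - 1)
        y1 <- min(h - 1, ceiling(max(poly[, 2])) + 1)
        xs <- rep((x0:x1), each = y1 - y0 + 1L)
        ys <- rep((y0:y1), x1 - x0 + 1L)
        inside <- pipMask(poly, xs, ys)
        rows <- ys[inside] + 1L; cols <- xs[inside] + 1L
        for (ch in 1:3) {
          idx <- cbind(rows, cols, rep(ch, length(rows)))
          px[idx] <- round(clamp255(.stromaRGB[ch] +
                                      rnorm(length(rows), 0, 8)))
        }
      }
    }
  })
  keep <- setdiff(seq_len(n), drop)
  gs <- GlandSet(glands@boundaries[keep], mpp = glands@mpp,
                 lumenAreas = glands@lumenAreas[keep], roiId = glands@roiId)
  roi2 <- RoiImage(px, mpp = roi@mpp, siteId = roi@siteId,
                   patientId = roi@patientId, classLabel = roi@classLabel,
                   roiId = roi@roiId)
  list(roi = roi2, glands = gs)
}

#' Apply a site effect to an ROI image
#'
#' Effects are applied in a fixed documented order: gland dropout, stain
#' rotation in the optical-density plane, additive RGB shift, contrast
#' scaling about 128, Gaussian blur; channel values are then rounded and
#' clamped to `[0, 255]`. The identity effect returns the input
#' bit-identical.
#'
#' @param roi a [RoiImage-class].
#' @param effect a [siteEffect()] description.
#' @param glands the ground-truth [GlandSet-class]; required when
#'   `glandDropoutRate > 0` (dropout repaints gland geometry, which cannot
#'   be recovered from pixels alone).
#' @param seed integer seed (used by dropout).
#' @return A [RoiImage-class] with the effect's `siteId` stamped on.
#' @export
applySiteEffect <- function(roi, effect, glands = NULL, seed = 1L) {
  stopifnot(inherits(effect, "SiteEffect"))
  if (isIdentityEffect(effect)) {
    roi@siteId <- effect$siteId
    return(roi)
  }
  if (effect$glandDropoutRate > 0) {
    if (is.null(glands))
      stop("glandDropoutRate > 0 requires the ground-truth glands")
    roi <- dropGlands(roi, glands, effect$glandDropoutRate, seed)$roi
  }
  px <- imagePixels(roi)
  if (effect$stainRotationDeg != 0) {
    od <- -log10((px + 1) / 256)
    B <- .stainBasis()
    a <- od[, , 1] * B[1, 1] + od[, , 2] * B[2, 1] + od[, , 3] * B[3, 1]
    b <- od[, , 1] * B[1, 2] + od[, , 2] * B[2, 2] + od[, , 3] * B[3, 2]
    th <- effect$stainRotationDeg * pi / 180
    a2 <- a * cos(th) - b * sin(th)
    b2 <- a * sin(th) + b * cos(th)
    for (ch in 1:3)
      od[, , ch] <- od[, , ch] + (a2 - a) * B[ch, 1] + (b2 - b) * B[ch, 2]
    px <- clamp255(256 * 10^(-od) - 1)
  }
  if (any(effect$rgbShift != 0))
    for (ch in 1:3) px[, , ch] <- px[, , ch] + effect$rgbShift[ch]
  if (effect$contrastScale != 1)
    px <- 128 + (px - 128) * effect$contrastScale
  px <- clamp255(px)
  if (effect$blurSigmaPx > 0) {
    ebi <- EBImage::Image(aperm(px, c(2, 1, 3)) / 255, colormode = "Color")
    ebi <- EBImage::gblur(ebi, sigma = effect$blurSigmaPx)
    px <- clamp255(aperm(as.array(ebi), c(2, 1, 3)) * 255)
  }
  RoiImage(round(px), mpp = roi@mpp, siteId = effect$siteId,
           patientId = roi@patientId, classLabel = roi@classLabel,
           roiId = roi@roiId)
}
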