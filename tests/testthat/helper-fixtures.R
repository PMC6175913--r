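# Shared fixtures, built in code at test time.

# small ROI with few glands; cached per session since several files reuse it
.fixtureEnv <- new.env()

smallRoi <- function() {
  if (is.null(.fixtureEnv$smallRoi))
    .fixtureEnv$smallRoi <- simulateRoi("noncancer", imageSize = c(256L, 256L),
                                        nGlands = 12L, seed = 42L)
  .fixtureEnv$smallRoi
}

# an image tiled from exactly four well-separated colors
fourColorRoi <- function() {
  cols <- rbind(c(30, 30, 30), c(200, 120, 180), c(140, 200, 140),
                c(250, 250, 250))
  px <- array(0, c(64, 64, 3))
  block <- matrix(rep(rep(1:4, each = 16), 64), 64, 64, byrow = TRUE)
  for (ch in 1:3) px[, , ch] <- matrix(cols[block, ch], 64, 64)
  list(roi = RoiImage(px, mpp = 4), colors = cols, assignment = block)
}

# white ellipses on a pink background
ellipsesRoi <- function(centers, a = 10, b = 6) {
  px <- array(0, c(128, 128, 3))
  pink <- c(225, 160, 200)
  for (ch in 1:3) px[, , ch] <- pink[ch]
  xs <- matrix(rep(0:127, each = 128), 128, 128)
  ys <- matrix(rep(0:127, 128), 128, 128)
  for (i in seq_len(nrow(centers))) {
    m <- ((xs - centers[i, 1]) / a)^2 + ((ys - centers[i, 2]) / b)^2 <= 1
    for (ch in 1:3) {
      pl <- px[, , ch]; pl[m] <- 255; px[, , ch] <- pl
    }
  }
  RoiImage(px, mpp = 4)
}

# regular polygon boundary (approximate circle)
circleBoundary <- function(cx = 0, cy = 0, r = 10, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(t), cy + r * sin(t))
}

ellipseBoundary <- function(cx = 0, cy = 0, a = 12, b = 5, phi = 0, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + a * cos(t) * cos(phi) - b * sin(t) * sin(phi),
        cy + a * cos(t) * sin(phi) + b * sin(t) * cos(phi))
}

rotateBoundary <- function(b, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b %*% t(R)
}

# feature table used by several selection/evaluation tests: 5 site-confounded
# unstable features (strong spurious pooled separation), 5 moderate stable
# discriminative features, 10 noise features
confoundedTable <- function(seed, nSites = 4L, nRegions = 40L) {
  sh <- matrix(0, 5, nSites, dimnames = list(as.character(1:5), NULL))
  sh[, seq(1, nSites, by = 2)] <- 6
  bal <- rep(c(0.9, 0.1), length.out = nSites)
  simulateFeatureTable(nSites = nSites, nRegionsPerSite = nRegions,
                       nFeatures = 20L, classBalance = bal,
                       discriminative = setNames(rep(1.2, 5),
                                                 as.character(6:10)),
                       siteShifts = sh, seed = seed)
}
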