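# Polygon and scalar utilities shared across feature families.
# Coordinates follow the package convention: 0-based pixels, x rightward,
# y downward; polygons are open vertex lists closed implicitly.

signedPolygonArea <- function(b) {
  x <- b[, 1]; y <- b[, 2]
  j <- c(seq_len(nrow(b))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygonArea <- function(b) abs(signedPolygonArea(b))

polygonCentroid <- function(b) {
  a <- signedPolygonArea(b)
  if (abs(a) < 1e-12) return(colMeans(b))
  x <- b[, 1]; y <- b[, 2]
  j <- c(seq_len(nrow(b))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

polygonPerimeter <- function(b) {
  j <- c(seq_len(nrow(b))[-1], 1L)
  sum(sqrt(rowSums((b[j, , drop = FALSE] - b)^2)))
}

convexHullPerimeter <- function(b) {
  h <- grDevices::chull(b)
  polygonPerimeter(b[h, , drop = FALSE])
}

# Exact raw moments m_pq (p + q <= maxOrder) of the polygon interior via
# triangle-fan decomposition from the origin; each triangle (0, a, b)
# contributes cross(a,b) * int over the unit simplex of
# (a_x u + b_x v)^p (a_y u + b_y v)^q, expanded with binomials and
# int u^m v^n = m! n! / (m + n + 2)!.
polygonMoments <- function(b, maxOrder = 3L) {
  if (signedPolygonArea(b) < 0) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
  n <- nrow(b)
  jn <- c(seq_len(n)[-1], 1L)
  ax <- b[, 1]; ay <- b[, 2]
  bx <- b[jn, 1]; by <- b[jn, 2]
  cr <- ax * by - bx * ay
  m <- matrix(0, maxOrder + 1L, maxOrder + 1L,
              dimnames = list(paste0("p", 0:maxOrder), paste0("q", 0:maxOrder)))
  for (p in 0:maxOrder) for (q in 0:(maxOrder - p)) {
    acc <- 0
    for (i in 0:p) for (j in 0:q) {
      coef <- choose(p, i) * choose(q, j) *
        factorial(i + j) * factorial(p + q - i - j) / factorial(p + q + 2)
      acc <- acc + coef * sum(cr * ax^i * bx^(p - i) * ay^j * by^(q - j))
    }
    m[p + 1L, q + 1L] <- acc
  }
  m
}

# Hu's seven moment invariants of the polygon interior, computed from exact
# central moments so that rotation invariance holds to machine precision.
huMoments <- function(b) {
  ctr <- polygonCentroid(b)
  bc <- sweep(b, 2, ctr)
  m <- polygonMoments(bc, 3L)
  mu00 <- m[1, 1]
  if (mu00 <= 0) stop("degenerate polygon: zero area")
  eta <- function(p, q) m[p + 1L, q + 1L] / mu00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

# Resample a closed polygon boundary to n points equally spaced in arc
# length, starting at the first vertex.
resampleBoundary <- function(b, n = 128L) {
  m <- nrow(b)
  jn <- c(seq_len(m)[-1], 1L)
  seg <- sqrt(rowSums((b[jn, , drop = FALSE] - b)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[m + 1L]
  if (total <= 0) stop("degenerate boundary: zero perimeter")
  s <- (seq_len(n) - 1L) / n * total
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (s - cum[idx]) / pmax(seg[idx], 1e-300)
  b[idx, , drop = FALSE] +
    (b[jn[idx], , drop = FALSE] - b[idx, , drop = FALSE]) * frac
}

circleFrom2 <- function(p, q) {
  list(ctr = (p + q) / 2, r = sqrt(sum((p - q)^2)) / 2)
}

circleFrom3 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    # collinear: fall back to the widest 2-point circle
    cands <- list(circleFrom2(a, b), circleFrom2(a, c), circleFrom2(b, c))
    return(cands[[which.max(vapply(cands, `[[`, numeric(1), "r"))]])
  }
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
  list(ctr = c(ux, uy), r = sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
}

inCircle <- function(circ, p, tol = 1e-9) {
  sqrt(sum((p - circ$ctr)^2)) <= circ$r * (1 + tol) + tol
}

# Minimum enclosing circle (Welzl, incremental, deterministic point order).
minEnclosingCircle <- function(P) {
  P <- unique(P)
  n <- nrow(P)
  if (n == 1L) return(list(ctr = P[1, ], r = 0))
  circ <- circleFrom2(P[1, ], P[2, ])
  if (n == 2L) return(circ)
  for (i in 3:n) {
    if (inCircle(circ, P[i, ])) next
    circ <- circleFrom2(P[1, ], P[i, ])
    for (j in 2:(i - 1L)) {
      if (inCircle(circ, P[j, ])) next
      circ <- circleFrom2(P[i, ], P[j, ])
      for (k in seq_len(j - 1L)) {
        if (inCircle(circ, P[k, ])) next
        circ <- circleFrom3(P[i, ], P[j, ], P[k, ])
      }
    }
  }
  circ
}

# Box-counting fractal dimension of a boundary curve: the boundary is
# densely resampled, scaled to the unit square, and occupied cells are
# counted over dyadic grids; the dimension is the slope of log N vs log 1/s.
boxCountDimension <- function(b, nResample = 512L, levels = 2:6) {
  pts <- resampleBoundary(b, nResample)
  rng <- apply(pts, 2, range)
  ext <- max(rng[2, ] - rng[1, ])
  if (ext <= 0) return(0)
  u <- sweep(sweep(pts, 2, rng[1, ]), 2, ext, "/")
  ns <- vapply(levels, function(l) {
    g <- 2^l
    cells <- floor(pmin(u, 1 - 1e-12) * g)
    length(unique(cells[, 1] * g + cells[, 2]))
  }, numeric(1))
  stats::coef(stats::lm(log(ns) ~ log(2^levels)))[[2]]
}

pointInPolygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (((yi > pt[2]) != (yj > pt[2])) &&
        (pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)) inside <- !inside
    j <- i
  }
  inside
}

# Aggregation helpers -------------------------------------------------------

# min/max ratio; identical values give 1, zero max gives 0.
minMaxRatio <- function(v) {
  mx <- max(v); mn <- min(v)
  if (mx == mn) return(1)
  if (mx == 0) return(0)
  mn / mx
}

# Disorder aggregate: 1 - 1/(1 + sd/mean); degenerate (near-zero mean or a
# single value) gives 0.
disorderStat <- function(v) {
  if (length(v) < 2L) return(0)
  m <- mean(v)
  if (!is.finite(m) || abs(m) < 1e-12) return(0)
  s <- sd(v)
  1 - 1 / (1 + s / abs(m))
}

# The four-aggregate summary used by the global-graph family.
aggregate4 <- function(v) {
  if (length(v) == 0L) return(c(mean = 0, std = 0, minmax = 0, disorder = 0))
  c(mean = mean(v), std = if (length(v) > 1L) sd(v) else 0,
    minmax = minMaxRatio(v), disorder = disorderStat(v))
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Deterministic child seeds, kept within 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629) + 1L
}
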