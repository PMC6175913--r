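# Delaunay triangulation (Bowyer-Watson incremental insertion) and its
# Voronoi dual. Written for the gland-centroid scale (tens to a few hundred
# points); correctness is checked in the test suite against the
# empty-circumcircle property and brute-force oracles.

circumcircle2 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-300) return(NULL)
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

#' Delaunay triangulation of a point set
#'
#' Incremental Bowyer-Watson triangulation. Points on a common circle are
#' resolved by a strict in-circle test, which always yields a valid (if not
#' unique) triangulation.
#'
#' @param xy numeric `n x 2` matrix of point coordinates, `n >= 3`.
#' @return A list with `triangles` (`k x 3` matrix of point indices) and
#'   `circumcenters` (`k x 2` matrix).
#' @export
delaunayTriangulation <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3L) stop("need at least 3 points for a triangulation")
  ctr <- colMeans(xy)
  rad <- max(sqrt(rowSums(sweep(xy, 2, ctr)^2)), 1) * 100
  super <- rbind(ctr + rad * c(0, 3), ctr + rad * c(-3, -2),
                 ctr + rad * c(3, -2))
  pts <- rbind(xy, super)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  ccs <- list(circumcircle2(super[1, ], super[2, ], super[3, ]))

  for (ip in seq_len(n)) {
    p <- pts[ip, ]
    bad <- vapply(seq_along(tris), function(t) {
      cc <- ccs[[t]]
      (p[1] - cc[1])^2 + (p[2] - cc[2])^2 < cc[3] * (1 - 1e-12)
    }, logical(1))
    if (!any(bad)) {
      # on/outside every circumcircle (cocircular tie): nudge test with a
      # non-strict comparison so insertion always proceeds
      bad <- vapply(seq_along(tris), function(t) {
        cc <- ccs[[t]]
        (p[1] - cc[1])^2 + (p[2] - cc[2])^2 <= cc[3] * (1 + 1e-12)
      }, logical(1))
    }
    badTris <- tris[bad]
    # boundary polygon: edges of bad triangles not shared by two bad triangles
    edges <- do.call(rbind, lapply(badTris, function(tr)
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    keep <- !(key %in% key[duplicated(key)])
    poly <- edges[keep, , drop = FALSE]
    tris <- tris[!bad]
    ccs <- ccs[!bad]
    for (e in seq_len(nrow(poly))) {
      tr <- c(poly[e, 1], poly[e, 2], ip)
      cc <- circumcircle2(pts[tr[1], ], pts[tr[2], ], pts[tr[3], ])
      if (is.null(cc)) next   # degenerate (collinear) sliver
      tris <- c(tris, list(tr))
      ccs <- c(ccs, list(cc))
    }
  }
  keep <- vapply(tris, function(tr) all(tr <= n), logical(1))
  tri <- do.call(rbind, tris[keep])
  if (is.null(tri)) stop("triangulation failed: points may be collinear")
  cc <- do.call(rbind, ccs[keep])[, 1:2, drop = FALSE]
  list(triangles = tri, circumcenters = cc)
}

delaunayEdges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  unique(e)
}

# clip a convex polygon against the half-plane a.x + b.y <= c
clipHalfPlane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] - cc
  jn <- c(seq_len(n)[-1], 1L)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- jn[i]
    inI <- d[i] <= 1e-9; inJ <- d[j] <= 1e-9
    if (inI) out <- rbind(out, poly[i, ])
    if (inI != inJ) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Voronoi cells of the interior points of a point set
#'
#' Builds the Voronoi polygon of every point that is not on the convex hull
#' (points on the hull have unbounded cells, which are excluded) by clipping
#' a bounding box against the perpendicular-bisector half-planes of all
#' other points. Robust to cocircular configurations such as regular grids.
#'
#' @param xy `n x 2` point matrix.
#' @param dt unused (kept for call-compatibility with the triangulation
#'   pipeline); cells are built directly from bisectors.
#' @return A named list of convex polygons (`k x 2` matrices), one per
#'   interior point, names are point indices.
#' @export
voronoiCells <- function(xy, dt = NULL) {
  n <- nrow(xy)
  rng <- apply(xy, 2, range)
  pad <- max(rng[2, ] - rng[1, ]) * 10 + 1
  cells <- list()
  for (i in seq_len(n)) {
    cell <- rbind(c(rng[1, 1] - pad, rng[1, 2] - pad),
                  c(rng[2, 1] + pad, rng[1, 2] - pad),
                  c(rng[2, 1] + pad, rng[2, 2] + pad),
                  c(rng[1, 1] - pad, rng[2, 2] + pad))
    p <- xy[i, ]
    ord <- order((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)
    for (j in ord) {
      if (j == i) next
      q <- xy[j, ]
      a <- q[1] - p[1]; b <- q[2] - p[2]
      cc <- (sum(q^2) - sum(p^2)) / 2
      cell <- clipHalfPlane(cell, a, b, cc)
      if (nrow(cell) < 3L) break
    }
    if (nrow(cell) < 3L) next
    # a cell still touching the padded box is unbounded: exclude it
    onBox <- abs(cell[, 1] - (rng[1, 1] - pad)) < 1e-6 |
      abs(cell[, 1] - (rng[2, 1] + pad)) < 1e-6 |
      abs(cell[, 2] - (rng[1, 2] - pad)) < 1e-6 |
      abs(cell[, 2] - (rng[2, 2] + pad)) < 1e-6
    if (any(onBox)) next
    cells[[as.character(i)]] <- cell
  }
  cells
}
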