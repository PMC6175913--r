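# Global graph family: 51 descriptors of gland arrangement computed from the
# Voronoi/Delaunay maps, minimum spanning tree, and neighborhood statistics
# of the gland centroids. All distances are in microns.

globalGraphFeatureNames <- function() {
  agg4 <- c("mean", "std", "minmax", "disorder")
  agg3 <- c("mean", "std", "disorder")
  c(paste0("graph_voronoi_area_", agg4),
    paste0("graph_voronoi_perimeter_", agg4),
    paste0("graph_voronoi_chord_", agg4),
    paste0("graph_delaunay_side_", agg4),
    paste0("graph_delaunay_area_", agg4),
    paste0("graph_mst_edge_", agg4),
    paste0("graph_knn3_dist_", agg4),
    paste0("graph_knn5_dist_", agg4),
    paste0("graph_knn7_dist_", agg4),
    paste0("graph_neighbors_40um_", agg3),
    paste0("graph_neighbors_60um_", agg3),
    paste0("graph_neighbors_80um_", agg3),
    paste0("graph_neighbors_100um_", agg3),
    "graph_gland_density_hull", "graph_gland_density_bbox",
    "graph_hull_bbox_ratio")
}

#' Global graph features (51 values)
#'
#' Voronoi polygon statistics (area, perimeter, chord lengths; unbounded
#' cells excluded), Delaunay statistics (edge length, triangle area),
#' minimum-spanning-tree edge statistics, distances to the 3/5/7 nearest
#' neighbors, neighbor counts within 40/60/80/100 micron radii, and three
#' density measurements (glands per square millimetre of convex hull and of
#' bounding box, and their area ratio). The scalar aggregates are mean,
#' standard deviation, min/max ratio and the disorder statistic
#' `1 - 1/(1 + std/mean)`.
#'
#' @param centroidsUm `n x 2` matrix of gland centroids in microns,
#'   `n >= 4`, not all collinear.
#' @return Named numeric vector of length 51.
#' @export
globalGraphFeatures <- function(centroidsUm) {
  xy <- as.matrix(centroidsUm)
  n <- nrow(xy)
  if (n < 4L) stop("insufficient glands for graph features (need >= 4)")
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2L)
    stop("insufficient glands for graph features (centroids are collinear)")

  dt <- delaunayTriangulation(xy)
  cells <- voronoiCells(xy, dt)
  vArea <- vapply(cells, polygonArea, numeric(1))
  vPerim <- vapply(cells, polygonPerimeter, numeric(1))
  vChord <- unlist(lapply(cells, function(cl) as.numeric(dist(cl))))
  if (is.null(vChord)) vChord <- numeric(0)

  edges <- delaunayEdges(dt$triangles)
  dSide <- sqrt(rowSums((xy[edges[, 1], , drop = FALSE] -
                           xy[edges[, 2], , drop = FALSE])^2))
  dArea <- apply(dt$triangles, 1, function(tr)
    polygonArea(xy[tr, , drop = FALSE]))

  D <- as.matrix(dist(xy))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mstEdges <- igraph::E(igraph::mst(g))$weight

  Dsort <- apply(D, 1, function(r) sort(r)[-1])  # drop self (0)
  # Dsort is (n-1) x n: column i holds sorted neighbor distances of point i
  knnMean <- function(k) colMeans(Dsort[seq_len(min(k, n - 1L)), , drop = FALSE])
  neighCount <- function(rUm) colSums(D <= rUm) - 1L

  hullIdx <- grDevices::chull(xy)
  hullAreaMm2 <- polygonArea(xy[hullIdx, , drop = FALSE]) / 1e6
  rngX <- diff(range(xy[, 1])); rngY <- diff(range(xy[, 2]))
  bboxAreaMm2 <- rngX * rngY / 1e6

  out <- c(
    aggregate4(vArea), aggregate4(vPerim), aggregate4(vChord),
    aggregate4(dSide), aggregate4(dArea), aggregate4(mstEdges),
    aggregate4(knnMean(3)), aggregate4(knnMean(5)), aggregate4(knnMean(7)),
    aggregate4(neighCount(40))[c("mean", "std", "disorder")],
    aggregate4(neighCount(60))[c("mean", "std", "disorder")],
    aggregate4(neighCount(80))[c("mean", "std", "disorder")],
    aggregate4(neighCount(100))[c("mean", "std", "disorder")],
    if (hullAreaMm2 > 0) n / hullAreaMm2 else 0,
    if (bboxAreaMm2 > 0) n / bboxAreaMm2 else 0,
    if (bboxAreaMm2 > 0) (hullAreaMm2 / bboxAreaMm2) else 0
  )
  setNames(out, globalGraphFeatureNames())
}
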