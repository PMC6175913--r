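# Sub-graph family: glands are joined into a fixed-radius geometric graph on
# their centroids; 26 statistics describe the connected components.

subgraphFeatureNames <- c(
  "subgraph_edge_length_mean", "subgraph_edge_length_std",
  "subgraph_edge_length_skewness", "subgraph_edge_length_kurtosis",
  "subgraph_avg_eccentricity", "subgraph_p90_eccentricity",
  "subgraph_avg_diameter", "subgraph_p90_diameter",
  "subgraph_avg_radius", "subgraph_p90_radius",
  "subgraph_avg_path_length", "subgraph_p90_path_length",
  "subgraph_clustering_c", "subgraph_clustering_d", "subgraph_clustering_e",
  "subgraph_giant_ratio", "subgraph_isolated_pct",
  "subgraph_n_end_nodes", "subgraph_n_central_nodes",
  "subgraph_n_components", "subgraph_avg_degree",
  "subgraph_component_size_mean", "subgraph_component_size_std",
  "subgraph_component_size_minmax", "subgraph_component_size_disorder",
  "subgraph_n_edges"
)

#' Build gland sub-graphs (fixed-radius geometric graph)
#'
#' Two glands are connected iff their centroid distance is at most
#' `connectionRadiusUm`; sub-graphs are the connected components. Isolated
#' glands form singleton components.
#'
#' @param centroidsUm `n x 2` matrix of gland centroids in microns.
#' @param connectionRadiusUm connection radius in microns (default 200).
#' @return A list with `membership` (component id per gland), `edges`
#'   (`m x 2` index matrix), `edgeLengths` (microns), `n` and
#'   `radiusUm`.
#' @export
buildSubgraphs <- function(centroidsUm, connectionRadiusUm = 200) {
  xy <- as.matrix(centroidsUm)
  n <- nrow(xy)
  if (n < 1L) stop("need at least one centroid")
  if (n == 1L)
    return(list(membership = 1L, edges = matrix(0L, 0, 2),
                edgeLengths = numeric(0), n = 1L,
                radiusUm = connectionRadiusUm))
  D <- as.matrix(dist(xy))
  adj <- which(upper.tri(D) & D <= connectionRadiusUm, arr.ind = TRUE)
  dimnames(adj) <- NULL
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(adj) > 0L) g <- igraph::add_edges(g, t(adj))
  comp <- igraph::components(g)
  list(membership = as.integer(comp$membership),
       edges = adj, edgeLengths = D[adj], n = n,
       radiusUm = connectionRadiusUm)
}

subgraphIgraph <- function(partition) {
  g <- igraph::make_empty_graph(n = partition$n, directed = FALSE)
  if (nrow(partition$edges) > 0L)
    g <- igraph::add_edges(g, t(partition$edges))
  g
}

#' Sub-graph features (26 values)
#'
#' Statistics over the connected components of the gland proximity graph:
#' edge-length moments, eccentricity/diameter/radius (average and 90th
#' percentile, in hops), average and 90th-percentile path length over
#' connected pairs, three clustering coefficients (C: mean local clustering
#' over nodes of degree >= 2; D: mean local clustering over all nodes,
#' degenerate nodes as 0; E: global transitivity), giant-component ratio,
#' fraction of isolated glands, numbers of end and central nodes, component
#' count, average degree, component-size statistics and edge count.
#' All-isolated partitions yield the documented degenerate value 0 for path
#' and clustering quantities.
#'
#' @param partition result of [buildSubgraphs()].
#' @return Named numeric vector of length 26.
#' @export
subgraphFeatures <- function(partition) {
  g <- subgraphIgraph(partition)
  n <- partition$n
  el <- partition$edgeLengths
  zmom <- function(x, f) {
    if (length(x) < 2L || sd(x) == 0) return(0)
    v <- f(x); if (!is.finite(v)) 0 else v
  }
  edgeStats <- c(
    if (length(el)) mean(el) else 0,
    if (length(el) > 1L) sd(el) else 0,
    zmom(el, e1071::skewness),
    zmom(el, e1071::kurtosis)
  )

  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  sizes <- as.numeric(comp$csize)
  ecc <- suppressWarnings(igraph::eccentricity(g))

  perComp <- function(f) vapply(seq_len(comp$no), function(ci) {
    e <- ecc[comp$membership == ci]
    f(e)
  }, numeric(1))
  compDiam <- perComp(max)
  compRad <- perComp(min)

  Dh <- igraph::distances(g)
  pl <- Dh[upper.tri(Dh)]
  pl <- pl[is.finite(pl)]
  pathAvg <- if (length(pl)) mean(pl) else 0
  pathP90 <- if (length(pl)) as.numeric(quantile(pl, 0.9)) else 0

  locC <- suppressWarnings(igraph::transitivity(g, type = "local"))
  hasDeg2 <- deg >= 2
  clustC <- if (any(hasDeg2)) mean(locC[hasDeg2], na.rm = TRUE) else 0
  if (!is.finite(clustC)) clustC <- 0
  locD <- locC; locD[!is.finite(locD)] <- 0
  clustD <- if (n > 0) mean(locD) else 0
  clustE <- suppressWarnings(igraph::transitivity(g, type = "global"))
  if (!is.finite(clustE)) clustE <- 0

  nCentral <- sum(vapply(seq_len(n), function(i)
    ecc[i] == compRad[comp$membership[i]], logical(1)))

  out <- c(
    edgeStats,
    mean(ecc), as.numeric(quantile(ecc, 0.9)),
    mean(compDiam), as.numeric(quantile(compDiam, 0.9)),
    mean(compRad), as.numeric(quantile(compRad, 0.9)),
    pathAvg, pathP90,
    clustC, clustD, clustE,
    max(sizes) / n,
    sum(deg == 0) / n,
    sum(deg == 1),
    nCentral,
    comp$no,
    mean(deg),
    aggregate4(sizes),
    nrow(partition$edges)
  )
  setNames(out, subgraphFeatureNames)
}
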