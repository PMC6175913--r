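# Orientation disorder family: per sub-graph, an 18 x 18 co-occurrence
# matrix of gland orientation angle bins (10-degree bins over [0, 180)) is
# populated from all unordered pairs of co-member glands (counted
# symmetrically), reduced to 13 co-occurrence statistics, and aggregated
# across sub-graphs by mean, std and range (39 features).

disorderAggNames <- c("mean", "std", "range")

disorderFeatureNames <- function() {
  as.vector(vapply(glcmStatNames, function(s)
    paste0("disorder_", disorderAggNames, "_tensor_", s), character(3)))
}

orientationBin <- function(angleDeg) {
  as.integer(pmin(pmax(floor(angleDeg / 10) + 1, 1), 18))
}

#' Orientation co-occurrence matrix of one sub-graph
#'
#' Entry (i, j) counts how many times a gland of orientation bin i co-occurs
#' in the sub-graph with a gland of orientation bin j; every unordered pair
#' of distinct glands contributes symmetrically, so the total count equals
#' the number of ordered pairs.
#'
#' @param bins integer orientation bins (1..18) of the member glands.
#' @return An 18 x 18 symmetric count matrix.
#' @export
orientationCooccurrence <- function(bins) {
  M <- matrix(0, 18L, 18L)
  m <- length(bins)
  if (m < 2L) return(M)
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    M[bins[a], bins[b]] <- M[bins[a], bins[b]] + 1
    M[bins[b], bins[a]] <- M[bins[b], bins[a]] + 1
  }
  M
}

#' Gland orientation disorder features (39 values)
#'
#' For every sub-graph with at least two glands, the 18 x 18 orientation
#' co-occurrence matrix is count-normalized and reduced to the 13
#' co-occurrence statistics; each statistic is aggregated across sub-graphs
#' by mean, standard deviation and range. If no sub-graph has two or more
#' glands, all 39 features take the documented degenerate value 0.
#'
#' @param glands a [GlandSet-class].
#' @param partition result of [buildSubgraphs()] on the same glands.
#' @return Named numeric vector of length 39.
#' @export
disorderFeatures <- function(glands, partition) {
  nm <- disorderFeatureNames()
  angles <- vapply(boundaries(glands, units = "um"), glandOrientation,
                   numeric(1))
  bins <- orientationBin(angles)
  compIds <- unique(partition$membership)
  statRows <- list()
  for (ci in compIds) {
    memb <- which(partition$membership == ci)
    if (length(memb) < 2L) next
    M <- orientationCooccurrence(bins[memb])
    statRows[[length(statRows) + 1L]] <- cooccurrenceStats(M)
  }
  if (!length(statRows)) return(setNames(rep(0, 39L), nm))
  S <- do.call(rbind, statRows)
  out <- numeric(0)
  for (s in glcmStatNames) {
    v <- S[, s]
    out <- c(out, mean(v), if (length(v) > 1L) sd(v) else 0,
             diff(range(v)))
  }
  setNames(out, nm)
}
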