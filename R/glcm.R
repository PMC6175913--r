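# Co-occurrence matrix machinery shared by the Haralick texture family and
# the gland orientation-disorder family. Both families reduce a symmetric,
# count-normalized co-occurrence matrix to the same 13 statistics.

glcmStatNames <- c(
  "contrast_energy", "contrast_inverse_moment", "contrast_average",
  "contrast_variance", "contrast_entropy", "intensity_average",
  "intensity_variance", "intensity_entropy", "entropy", "energy",
  "correlation", "information_measure1", "information_measure2"
)

# 13 statistics of a normalized co-occurrence matrix P (rows/cols are
# intensity or orientation bins). Entropies use log2 with 0 log 0 = 0;
# degenerate denominators (zero marginal variance, zero marginal entropy)
# yield the documented value 0.
cooccurrenceStats <- function(P) {
  G <- nrow(P)
  tot <- sum(P)
  if (tot <= 0) return(setNames(rep(0, 13L), glcmStatNames))
  P <- P / tot
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)

  k <- abs(i - j)
  pxmy <- vapply(0:(G - 1L), function(d) sum(P[k == d]), numeric(1))
  s <- i + j
  pxpy <- vapply(2:(2L * G), function(d) sum(P[s == d]), numeric(1))

  xlog2 <- function(p) ifelse(p > 0, log2(p), 0)
  kv <- 0:(G - 1L)
  sv <- 2:(2L * G)

  contrast_average <- sum(kv * pxmy)
  contrast_energy <- sum(kv^2 * pxmy)
  contrast_inverse_moment <- sum(pxmy / (1 + kv^2))
  contrast_variance <- sum((kv - contrast_average)^2 * pxmy)
  contrast_entropy <- -sum(pxmy * xlog2(pxmy))
  intensity_average <- sum(sv * pxpy)
  intensity_variance <- sum((sv - intensity_average)^2 * pxpy)
  intensity_entropy <- -sum(pxpy * xlog2(pxpy))
  entropy <- -sum(P * xlog2(P))
  energy <- sum(P^2)

  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))
  correlation <- if (sx > 0 && sy > 0)
    (sum(i * j * P) - mux * muy) / (sx * sy) else 0

  hx <- -sum(px * xlog2(px)); hy <- -sum(py * xlog2(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * xlog2(pxy))
  hxy2 <- -sum(pxy * xlog2(pxy))
  information_measure1 <- if (max(hx, hy) > 0)
    (entropy - hxy1) / max(hx, hy) else 0
  information_measure2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))

  setNames(c(contrast_energy, contrast_inverse_moment, contrast_average,
             contrast_variance, contrast_entropy, intensity_average,
             intensity_variance, intensity_entropy, entropy, energy,
             correlation, information_measure1, information_measure2),
           glcmStatNames)
}

# Symmetric gray-level co-occurrence counts of an integer-valued matrix
# (levels 1..G) summed over the four unit offsets (0, 45, 90, 135 degrees);
# each pair is counted in both orders.
grayCooccurrence <- function(g, G) {
  nr <- nrow(g); nc <- ncol(g)
  counts <- matrix(0, G, G)
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    a <- g[r1, c1, drop = FALSE]
    b <- g[r1 + dr, c1 + dc, drop = FALSE]
    tab <- tabulate((a - 1L) * G + b, nbins = G * G)
    m <- matrix(tab, G, G, byrow = TRUE)
    counts <- counts + m + t(m)
  }
  counts
}
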