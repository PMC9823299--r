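# Density-based clustering used in two places: 1-D consensus filtering of
# internal-coordinate estimates during decoding (min_samples = 1, so every
# estimate belongs to a cluster and "the biggest cluster" is always defined)
# and torsion-space clustering of conformer ensembles (classic DBSCAN with a
# minPts core condition on a precomputed distance matrix).

# 1-D DBSCAN with min_samples = 1: clusters are runs of sorted values whose
# successive gaps are <= eps.  Returns integer labels (1..k).
dbscan_linear_1d <- function(x, eps) {
  n <- length(x)
  if (n == 1L) return(1L)
  o <- order(x)
  gaps <- diff(x[o]) > eps
  lab_sorted <- cumsum(c(1L, as.integer(gaps)))
  labels <- integer(n)
  labels[o] <- lab_sorted
  labels
}

# Same on a 360-degree circle: a gap across the wrap point merges the first
# and last run.
dbscan_circular_1d <- function(x, eps) {
  n <- length(x)
  if (n == 1L) return(1L)
  xw <- ((x %% 360) + 360) %% 360
  o <- order(xw)
  gaps <- diff(xw[o]) > eps
  lab_sorted <- cumsum(c(1L, as.integer(gaps)))
  wrap_gap <- (xw[o][1] + 360 - xw[o][n]) > eps
  if (!wrap_gap && max(lab_sorted) > 1L)
    lab_sorted[lab_sorted == max(lab_sorted)] <- 1L
  labels <- integer(n)
  labels[o] <- lab_sorted
  match(labels, unique(labels[order(labels)]))
}

# pick the biggest cluster; ties broken by the cluster whose smallest member
# comes first in the (possibly circular) sort order -- deterministic
biggest_cluster <- function(labels) {
  tab <- table(labels)
  big <- as.integer(names(tab)[tab == max(tab)])
  if (length(big) > 1L) {
    firsts <- vapply(big, function(l) min(which(labels == l)), integer(1))
    big <- big[which.min(firsts)]
  }
  which(labels == big)
}

# Full DBSCAN on a precomputed distance matrix (Ester et al. semantics):
# points with >= min_samples neighbors within eps (self included) are cores;
# clusters are connected components of cores under the eps graph, border
# points join the cluster of a core neighbor, the rest are noise (label 0).
dbscan_matrix <- function(d, eps, min_samples = 5L) {
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}
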