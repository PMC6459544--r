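# Connected-pair and cluster analysis of dlc+ cells. Two dlc+ cells form a
# connected pair when their center distance is strictly less than
# 1.25 cell diameters ("less than" per the imaging definition, so a pair at
# exactly the threshold is NOT connected); clusters are the connected
# components of the pair graph, an isolated cell being a size-1 cluster.

# Core: adjacency + components for a point set at a distance cutoff.
cluster_engine <- function(x, y, cutoff) {
  n <- length(x)
  if (n == 0L) {
    return(list(n_pairs = 0L, pct_in_pairs = 0, sizes = integer(0),
                max_cluster = 0L, n_clusters = 0L))
  }
  if (n == 1L) {
    return(list(n_pairs = 0L, pct_in_pairs = 0, sizes = 1L,
                max_cluster = 1L, n_clusters = 1L))
  }
  d <- as.matrix(stats::dist(cbind(x, y)))
  adj <- d < cutoff
  diag(adj) <- FALSE
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  # union-find with path halving; `find` closes over `parent`
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1L])
      rb <- find(edges[k, 2L])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- as.integer(sort(table(roots), decreasing = TRUE))
  list(n_pairs = nrow(edges),
       pct_in_pairs = 100 * sum(rowSums(adj) > 0L) / n,
       sizes = sizes,
       max_cluster = max(sizes),
       n_clusters = length(sizes))
}

cluster_stats_of <- function(cells, threshold, mean_diameter) {
  stopifnot(is.data.frame(cells))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_ionopattern("invalid_input", "threshold must be > 0")
  }
  dlc <- cells[cells$dlc, , drop = FALSE]
  if (is.null(mean_diameter)) {
    mean_diameter <- if (nrow(dlc) > 0L) mean(dlc$diameter_um) else NA_real_
  }
  if (nrow(dlc) > 0L && (!is.finite(mean_diameter) || mean_diameter <= 0)) {
    stop_ionopattern("invalid_input", "mean_diameter must be positive")
  }
  eng <- cluster_engine(dlc$x_um, dlc$y_um, threshold * mean_diameter)
  structure(list(threshold = threshold, mean_diameter = mean_diameter,
                 n_connected_pairs = eng$n_pairs,
                 pct_cells_in_pairs = eng$pct_in_pairs,
                 cluster_sizes = eng$sizes, max_cluster = eng$max_cluster,
                 n_clusters = eng$n_clusters), class = "cluster_stats")
}

#' Connected dlc+ pairs below the contact threshold
#'
#' Counts unordered pairs of dlc+ cells whose center distance is strictly
#' less than `threshold` mean cell diameters, and the percentage of dlc+
#' cells belonging to at least one such pair (the headline statistic; the
#' raw pair count is also returned).
#'
#' @param cells Cell table of one embryo.
#' @param threshold Contact threshold in cell diameters (default 1.25).
#' @param mean_diameter Normalizing diameter in um; default is the mean
#'   recorded diameter of the embryo's dlc+ cells.
#' @return Object of class `cluster_stats` (see [decompose_clusters()]).
#' @export
connected_pairs <- function(cells, threshold = 1.25, mean_diameter = NULL) {
  cluster_stats_of(cells, threshold, mean_diameter)
}

#' Cluster decomposition of dlc+ cells
#'
#' Decomposes the dlc+ cells into connected components of the pair graph
#' whose edges join cells closer than `threshold` cell diameters. An
#' isolated cell is a cluster of size 1; `sum(cluster_sizes)` equals the
#' number of dlc+ cells; `max_cluster` is 0 when the embryo has no dlc+
#' cell.
#'
#' @inheritParams connected_pairs
#' @return Object of class `cluster_stats`: list with `threshold`,
#'   `mean_diameter`, `n_connected_pairs`, `pct_cells_in_pairs`,
#'   `cluster_sizes` (decreasing), `max_cluster`, `n_clusters`.
#' @export
decompose_clusters <- function(cells, threshold = 1.25, mean_diameter = NULL) {
  cluster_stats_of(cells, threshold, mean_diameter)
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf(
    "<cluster_stats> %d pairs (<%g diameters), %.1f%% of cells paired, %d clusters, max %d\n",
    x$n_connected_pairs, x$threshold, x$pct_cells_in_pairs, x$n_clusters,
    x$max_cluster))
  invisible(x)
}
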