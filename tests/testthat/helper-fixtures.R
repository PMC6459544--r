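# Fixture builders and independent brute-force oracles shared by the suite.
# Oracles deliberately avoid the code paths they check: plain double loops /
# outer() arithmetic instead of stats::dist, frontier BFS instead of
# union-find, arc-start minimization instead of the sorted-gap scan.

default_geometry <- function() {
  make_geometry(radius = 400, sector_center = -pi / 2,
                sector_halfwidth = 1.6875)
}

tiny_geometry <- function(radius = 120) {
  make_geometry(radius = radius, sector_center = -pi / 2,
                sector_halfwidth = pi)
}

tiny_preset <- function(name = "tiny", n_stem_mean = 80, ...) {
  condition_preset(name, n_stem_mean = n_stem_mean, ...)
}

# Hand-built cell table at given positions (one embryo).
make_cells <- function(x, y, diameter = 10, p63 = TRUE, dlc = TRUE,
                       brdu = FALSE, embryo_id = "e1", condition = "test") {
  n <- length(x)
  data.frame(embryo_id = rep_len(embryo_id, n),
             cell_id = sprintf("c%03d", seq_len(n)),
             x_um = x, y_um = y,
             diameter_um = rep_len(diameter, n),
             p63 = rep_len(p63, n), dlc = rep_len(dlc, n),
             brdu = rep_len(brdu, n),
             condition = rep_len(condition, n), stringsAsFactors = FALSE)
}

# ---- oracles ---------------------------------------------------------------

bf_pairwise_dist <- function(x, y) {
  sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
}

bf_nearest <- function(x, y) {
  d <- bf_pairwise_dist(x, y)
  diag(d) <- Inf
  apply(d, 1, min)
}

bf_pair_count <- function(x, y, cutoff) {
  n <- length(x)
  cnt <- 0L
  if (n >= 2L) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) < cutoff) cnt <- cnt + 1L
    }
  }
  cnt
}

# Connected-component sizes by frontier BFS on the adjacency matrix.
bf_cluster_sizes <- function(x, y, cutoff) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  adj <- bf_pairwise_dist(x, y) < cutoff
  diag(adj) <- FALSE
  unvisited <- rep(TRUE, n)
  sizes <- integer(0)
  while (any(unvisited)) {
    comp <- rep(FALSE, n)
    frontier <- rep(FALSE, n)
    frontier[which(unvisited)[1]] <- TRUE
    while (any(frontier)) {
      comp <- comp | frontier
      reach <- colSums(adj[frontier, , drop = FALSE]) > 0
      frontier <- reach & !comp
    }
    sizes <- c(sizes, sum(comp))
    unvisited <- unvisited & !comp
  }
  sort(sizes, decreasing = TRUE)
}

# Smallest arc (degrees) containing all angles: minimize over arc starts.
bf_min_arc_deg <- function(theta) {
  theta <- theta %% (2 * pi)
  widths <- vapply(theta, function(t0) max((theta - t0) %% (2 * pi)),
                   numeric(1))
  min(widths) * 180 / pi
}

# ---- cached full-scale cohort for recovery/acceptance tests ----------------

.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.cohort_cache$full)) {
    cfg <- cohort_config(
      presets = default_presets()[c("wild_type", "hom", "morphant",
                                    "overexpression")],
      n_embryos_per_condition = 20, seed = 101,
      geometry = default_geometry())
    cohort <- generate_cohort(cfg)
    .cohort_cache$full <- list(
      cells = cohort$cells, geometry = cohort$geometry,
      summary = summarize_cohort(cohort$cells, cohort$geometry))
  }
  .cohort_cache$full
}
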