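# Per-embryo pattern statistics: compartment counts, densities, diameters,
# normalized nearest-neighbour spacing, domain angle.

#' Compartmentalized cell counts with BrdU subsets
#'
#' Partitions one embryo's cells by their (dlc, p63) flags into keratinocyte
#' progenitors (dlc-p63+), ionocyte progenitors (dlc+p63+) and the rare
#' mislabel class (dlc+p63-), each with its BrdU+ subcount. The conservation
#' identity `n_p63 = n_kerat + n_iono` holds by construction.
#'
#' @param cells Cell table restricted to one embryo's counting region.
#' @return Object of class `compartment_counts`: a list with counts
#'   `n_p63, n_kerat, n_iono, n_mislabel` and BrdU subcounts
#'   `n_brdu_p63, n_brdu_kerat, n_brdu_iono, n_brdu_mislabel`.
#' @export
compartment_counts <- function(cells) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) > 0L && anyDuplicated(cells[c("embryo_id", "cell_id")])) {
    stop_ionopattern("integrity_error",
                     "duplicate cell_id within an embryo")
  }
  kerat <- cells$p63 & !cells$dlc
  iono <- cells$p63 & cells$dlc
  mis <- !cells$p63 & cells$dlc
  structure(list(
    n_p63 = sum(cells$p63),
    n_kerat = sum(kerat),
    n_iono = sum(iono),
    n_mislabel = sum(mis),
    n_brdu_p63 = sum(cells$brdu & cells$p63),
    n_brdu_kerat = sum(cells$brdu & kerat),
    n_brdu_iono = sum(cells$brdu & iono),
    n_brdu_mislabel = sum(cells$brdu & mis)), class = "compartment_counts")
}

#' Cell density in cells per square micrometer
#'
#' @param count Cell count (>= 0).
#' @param area Region area in um^2 (> 0).
#' @return Density in cells/um^2. The study's figures print densities
#'   multiplied by 1e4; use [format_density()] for that rendering.
#' @export
#' @examples
#' cell_density(10, 1e5) # 1e-4
cell_density <- function(count, area) {
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0) {
    stop_ionopattern("invalid_area", "area must be a positive number")
  }
  if (!is.numeric(count) || length(count) != 1L || count < 0) {
    stop_ionopattern("invalid_area", "count must be a non-negative number")
  }
  count / area
}

#' Render a density with the conventional 1e-4 cells/um^2 scaling
#' @param density Density in cells/um^2.
#' @param digits Decimal places.
#' @return A string such as `"2.13 x 10^-4 cells um^-2"`.
#' @export
format_density <- function(density, digits = 2) {
  sprintf("%.*f x 10^-4 cells um^-2", digits, density * 1e4)
}

#' Estimate the mean cell diameter of a set of cells
#'
#' The default estimator is the arithmetic mean of recorded diameters. For
#' data without annotated diameters, the alternative `"nearest_neighbour"`
#' estimator uses the mean nearest-neighbour center distance of the supplied
#' cells as a packing-based proxy.
#'
#' @param cells Cell table (often subset to dlc+ cells first).
#' @param method `"recorded"` (default) or `"nearest_neighbour"`.
#' @return Mean diameter in micrometers.
#' @export
estimate_mean_diameter <- function(cells,
                                   method = c("recorded", "nearest_neighbour")) {
  method <- match.arg(method)
  if (nrow(cells) == 0L) {
    stop_ionopattern("estimation_error", "no cells to estimate a diameter from")
  }
  if (method == "recorded") {
    return(mean(cells$diameter_um))
  }
  if (nrow(cells) < 2L) {
    stop_ionopattern("estimation_error",
                     "nearest-neighbour estimator needs at least 2 cells")
  }
  mean(nearest_neighbour_distances(cells$x_um, cells$y_um))
}

# Distance from each point to its nearest other point (O(n^2), vectorized).
nearest_neighbour_distances <- function(x, y) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  unname(apply(d, 1L, min))
}

#' Normalized nearest-neighbour spacing of dlc+ cells in the central area
#'
#' Focal cells are dlc+ cells whose distance from the embryo centroid is at
#' most `central_fraction` of the embryo diameter, i.e.
#' `central_fraction * radius` (40% of the diameter by default, the
#' literal reading of the imaging protocol). Each focal cell's nearest dlc+
#' neighbour may lie anywhere in the embryo; restricting neighbours to the
#' central region would bias distances upward at its edge. Every distance is
#' divided by the embryo's mean dlc+ cell diameter (override with
#' `mean_diameter`), yielding dimensionless spacings in cell-diameter units.
#'
#' @param cells Cell table of one embryo.
#' @param geometry An [make_geometry()] object.
#' @param central_fraction Fraction of the embryo diameter defining the
#'   central area (default 0.40).
#' @param mean_diameter Normalizing diameter in um; default is the mean
#'   recorded diameter of the embryo's dlc+ cells.
#' @return Object of class `spacing_stats`: list with `values` (per focal
#'   cell), `mean_norm_spacing`, `n_used`, `mean_diameter`, and `undefined`
#'   (TRUE when fewer than two dlc+ cells exist or no dlc+ cell is central).
#' @export
normalized_nearest_spacing <- function(cells, geometry,
                                       central_fraction = 0.40,
                                       mean_diameter = NULL) {
  stopifnot(is.data.frame(cells), inherits(geometry, "embryo_geometry"))
  if (!is.numeric(central_fraction) || central_fraction <= 0 ||
      central_fraction > 1) {
    stop_ionopattern("invalid_input", "central_fraction must lie in (0, 1]")
  }
  dlc <- cells[cells$dlc, , drop = FALSE]
  undefined <- structure(list(values = numeric(0),
                              mean_norm_spacing = NA_real_, n_used = 0L,
                              mean_diameter = NA_real_, undefined = TRUE),
                         class = "spacing_stats")
  if (nrow(dlc) < 2L) return(undefined)
  if (is.null(mean_diameter)) mean_diameter <- mean(dlc$diameter_um)
  if (!is.finite(mean_diameter) || mean_diameter <= 0) {
    stop_ionopattern("invalid_input", "mean_diameter must be positive")
  }
  nn <- nearest_neighbour_distances(dlc$x_um, dlc$y_um)
  r_c <- sqrt((dlc$x_um - geometry$centroid[1])^2 +
                (dlc$y_um - geometry$centroid[2])^2)
  focal <- r_c <= central_fraction * geometry$radius
  if (!any(focal)) return(undefined)
  vals <- nn[focal] / mean_diameter
  structure(list(values = vals, mean_norm_spacing = mean(vals),
                 n_used = sum(focal), mean_diameter = mean_diameter,
                 undefined = FALSE), class = "spacing_stats")
}

#' Angular width of the dlc+ ionocyte domain at the embryo centroid
#'
#' Converts dlc+ cell positions to polar angles about the centroid and
#' returns the width, in degrees, of the smallest circular arc containing
#' all of them: the complement of the largest angular gap between
#' consecutive cells. This equals the angle between the two centroid vectors
#' flanking the domain and is proportional to the domain's sector area.
#'
#' @param cells Cell table of one embryo.
#' @param geometry An [make_geometry()] object.
#' @return Angle in degrees; 0 for a single dlc+ cell; `NA` when the embryo
#'   has no dlc+ cell (undefined-angle flag).
#' @export
domain_angle <- function(cells, geometry) {
  stopifnot(is.data.frame(cells), inherits(geometry, "embryo_geometry"))
  dlc <- cells[cells$dlc, , drop = FALSE]
  if (nrow(dlc) == 0L) return(NA_real_)
  if (nrow(dlc) == 1L) return(0)
  theta <- sort(atan2(dlc$y_um - geometry$centroid[2],
                      dlc$x_um - geometry$centroid[1]))
  gaps <- diff(c(theta, theta[1] + 2 * pi))
  (2 * pi - max(gaps)) * 180 / pi
}
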