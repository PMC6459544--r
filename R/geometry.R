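#' Embryo geometry for the ventral counting region
#'
#' Describes one embryo as a circular lateral projection with the centroid at
#' the origin and a ventral counting sector in which cells are annotated. The
#' sector is the set of points whose polar angle lies within
#' `sector_halfwidth` of `sector_center` (angles in radians, measured
#' counterclockwise from the +x axis); its area is
#' `counting_area = sector_halfwidth * radius^2`, the circular-sector formula
#' (a halfwidth of `pi` gives the full disc, `pi * radius^2`).
#'
#' @param radius Embryo radius in micrometers (> 0).
#' @param sector_center Polar angle (radians) of the ventral midline.
#'   Default `-pi/2` (straight down).
#' @param sector_halfwidth Angular halfwidth (radians) of the counting
#'   sector, in `(0, pi]`. Default `pi` (full disc).
#' @param centroid Numeric length-2 centroid in micrometers. By convention
#'   the centroid is the origin; a non-zero centroid is honoured by all
#'   downstream statistics.
#'
#' @return An object of class `embryo_geometry`: a list with fields
#'   `centroid`, `radius`, `sector_center`, `sector_halfwidth`,
#'   `counting_area`.
#' @export
#' @examples
#' g <- make_geometry(radius = 400, sector_halfwidth = pi / 4)
#' g$counting_area # (pi/4) * 400^2
make_geometry <- function(radius, sector_center = -pi / 2,
                          sector_halfwidth = pi, centroid = c(0, 0)) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop_ionopattern("invalid_geometry", "radius must be a positive number")
  }
  if (!is.numeric(sector_halfwidth) || length(sector_halfwidth) != 1L ||
      !is.finite(sector_halfwidth) || sector_halfwidth <= 0 ||
      sector_halfwidth > pi) {
    stop_ionopattern("invalid_geometry",
                     "sector_halfwidth must lie in (0, pi]")
  }
  if (!is.numeric(sector_center) || length(sector_center) != 1L ||
      !is.finite(sector_center)) {
    stop_ionopattern("invalid_geometry", "sector_center must be a finite angle")
  }
  if (!is.numeric(centroid) || length(centroid) != 2L || any(!is.finite(centroid))) {
    stop_ionopattern("invalid_geometry", "centroid must be a numeric length-2 point")
  }
  structure(
    list(centroid = as.numeric(centroid),
         radius = as.numeric(radius),
         sector_center = as.numeric(sector_center),
         sector_halfwidth = as.numeric(sector_halfwidth),
         counting_area = as.numeric(sector_halfwidth) * as.numeric(radius)^2),
    class = "embryo_geometry")
}

#' @export
print.embryo_geometry <- function(x, ...) {
  cat(sprintf(
    "<embryo_geometry> radius %.1f um, sector %.3f +/- %.3f rad, area %.3g um^2\n",
    x$radius, x$sector_center, x$sector_halfwidth, x$counting_area))
  invisible(x)
}

# Smallest absolute angular deviation from a reference angle, in [0, pi].
angular_deviation <- function(theta, reference) {
  abs(((theta - reference + pi) %% (2 * pi)) - pi)
}

#' Convert a list of embryo geometries to the geometry table
#'
#' One row per embryo with columns
#' `embryo_id, cx_um, cy_um, radius_um, sector_center_rad,
#' sector_halfwidth_rad, area_um2`.
#'
#' @param geometries Named list of [make_geometry()] objects; names are
#'   embryo ids.
#' @return A data.frame, one row per embryo.
#' @export
geometry_table <- function(geometries) {
  stopifnot(is.list(geometries))
  if (length(geometries) == 0L) {
    return(data.frame(embryo_id = character(), cx_um = numeric(),
                      cy_um = numeric(), radius_um = numeric(),
                      sector_center_rad = numeric(),
                      sector_halfwidth_rad = numeric(),
                      area_um2 = numeric(), stringsAsFactors = FALSE))
  }
  ids <- names(geometries)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop_ionopattern("invalid_geometry", "geometries must be a named list")
  }
  do.call(rbind, lapply(ids, function(id) {
    g <- geometries[[id]]
    data.frame(embryo_id = id, cx_um = g$centroid[1], cy_um = g$centroid[2],
               radius_um = g$radius, sector_center_rad = g$sector_center,
               sector_halfwidth_rad = g$sector_halfwidth,
               area_um2 = g$counting_area, stringsAsFactors = FALSE)
  }))
}

# Rebuild an embryo_geometry from one row of the geometry table.
geometry_from_row <- function(row) {
  make_geometry(radius = row$radius_um,
                sector_center = row$sector_center_rad,
                sector_halfwidth = row$sector_halfwidth_rad,
                centroid = c(row$cx_um, row$cy_um))
}
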