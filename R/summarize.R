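#' Summarize every pattern statistic for one embryo
#'
#' Aggregates [compartment_counts()], per-compartment densities and BrdU
#' fractions, the mean dlc+ diameter, [normalized_nearest_spacing()],
#' [domain_angle()] and [decompose_clusters()] into a one-row data frame.
#' Statistics undefined for the embryo (no dlc+ cells, zero-count
#' compartments) are reported as `NA`.
#'
#' @param cells Cell table of one embryo.
#' @param geometry An [make_geometry()] object for that embryo.
#' @param central_fraction Central-area fraction for the spacing statistic.
#' @param pair_threshold Contact threshold (cell diameters) for pairs and
#'   clusters.
#' @param embryo_id,condition Identifiers; defaulted from `cells` when the
#'   table is non-empty.
#' @return A one-row data.frame (see column list in the source); densities
#'   are in cells/um^2, fractions in percent, spacing in cell diameters,
#'   angle in degrees.
#' @export
summarize_embryo <- function(cells, geometry, central_fraction = 0.40,
                             pair_threshold = 1.25, embryo_id = NULL,
                             condition = NULL) {
  stopifnot(is.data.frame(cells), inherits(geometry, "embryo_geometry"))
  if (nrow(cells) > 0L) {
    ids <- unique(cells$embryo_id)
    if (length(ids) != 1L) {
      stop_ionopattern("integrity_error",
                       "summarize_embryo expects a single embryo, got %d ids",
                       length(ids))
    }
    embryo_id <- embryo_id %||% ids
    condition <- condition %||% unique(cells$condition)[1]
  } else {
    embryo_id <- embryo_id %||% NA_character_
    condition <- condition %||% NA_character_
  }
  cc <- compartment_counts(cells)
  area <- geometry$counting_area
  pct <- function(part, whole) if (whole > 0L) 100 * part / whole else NA_real_
  dlc <- cells[cells$dlc, , drop = FALSE]
  mean_diam <- if (nrow(dlc) > 0L) mean(dlc$diameter_um) else NA_real_
  sp <- normalized_nearest_spacing(cells, geometry,
                                   central_fraction = central_fraction)
  cl <- decompose_clusters(cells, threshold = pair_threshold)
  data.frame(
    embryo_id = embryo_id, condition = condition,
    n_p63 = cc$n_p63, n_kerat = cc$n_kerat, n_iono = cc$n_iono,
    n_mislabel = cc$n_mislabel,
    n_brdu_p63 = cc$n_brdu_p63, n_brdu_kerat = cc$n_brdu_kerat,
    n_brdu_iono = cc$n_brdu_iono, n_brdu_mislabel = cc$n_brdu_mislabel,
    pct_brdu_p63 = pct(cc$n_brdu_p63, cc$n_p63),
    pct_brdu_kerat = pct(cc$n_brdu_kerat, cc$n_kerat),
    pct_brdu_iono = pct(cc$n_brdu_iono, cc$n_iono),
    density_p63 = cc$n_p63 / area,
    density_kerat = cc$n_kerat / area,
    density_iono = cc$n_iono / area,
    density_mislabel = cc$n_mislabel / area,
    mean_diameter_um = mean_diam,
    mean_norm_spacing = sp$mean_norm_spacing,
    n_spacing_cells = sp$n_used,
    domain_angle_deg = domain_angle(cells, geometry),
    n_connected_pairs = cl$n_connected_pairs,
    pct_cells_in_pairs = if (nrow(dlc) > 0L) cl$pct_cells_in_pairs else NA_real_,
    n_clusters = cl$n_clusters,
    max_cluster = cl$max_cluster,
    counting_area_um2 = area,
    stringsAsFactors = FALSE)
}

#' Summarize every embryo of a cohort
#'
#' @param cells Cell table over any number of embryos.
#' @param geometry Geometry table (one row per embryo) as produced by
#'   [generate_cohort()] or [read_geometry_table()].
#' @inheritParams summarize_embryo
#' @return A data.frame with one row per embryo in the geometry table;
#'   embryos without any annotated cell get all-zero counts.
#' @export
summarize_cohort <- function(cells, geometry, central_fraction = 0.40,
                             pair_threshold = 1.25) {
  stopifnot(is.data.frame(cells), is.data.frame(geometry))
  rows <- lapply(seq_len(nrow(geometry)), function(i) {
    row <- geometry[i, , drop = FALSE]
    g <- geometry_from_row(row)
    sub <- cells[cells$embryo_id == row$embryo_id, , drop = FALSE]
    summarize_embryo(sub, g, central_fraction = central_fraction,
                     pair_threshold = pair_threshold,
                     embryo_id = row$embryo_id)
  })
  if (length(rows) == 0L) {
    # zero-row frame with the full schema
    out <- summarize_embryo(empty_cell_table(), make_geometry(1))
    return(out[0L, , drop = FALSE])
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
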