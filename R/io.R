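# CSV and JSON I/O. Cell and geometry tables are RFC-4180 CSV, UTF-8,
# '.' decimal separator; marker flags are written as 0/1 and accepted as
# 0/1 or TRUE/FALSE (any case) on read. Validation errors name the
# offending file line (header = line 1).

cell_table_columns <- c("embryo_id", "cell_id", "x_um", "y_um",
                        "diameter_um", "p63", "dlc", "brdu", "condition")
geometry_table_columns <- c("embryo_id", "cx_um", "cy_um", "radius_um",
                            "sector_center_rad", "sector_halfwidth_rad",
                            "area_um2")

parse_flag <- function(x, column, path) {
  out <- rep(NA, length(x))
  low <- tolower(trimws(x))
  out[low %in% c("1", "true", "t")] <- TRUE
  out[low %in% c("0", "false", "f")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop_ionopattern("schema_error",
                     "%s line %d: column '%s' has non-flag value '%s'",
                     path, bad[1] + 1L, column, x[bad[1]])
  }
  as.logical(out)
}

parse_num <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0L || anyNA(x)) {
    line <- if (length(bad) > 0L) bad[1] else which(is.na(x))[1]
    stop_ionopattern("schema_error",
                     "%s line %d: column '%s' has non-numeric value '%s'",
                     path, line + 1L, column, x[line])
  }
  out
}

check_columns <- function(found, wanted, path) {
  missing <- setdiff(wanted, found)
  if (length(missing) > 0L) {
    stop_ionopattern("schema_error", "%s: missing column(s) %s",
                     path, paste(missing, collapse = ", "))
  }
}

#' Read an annotated cell table
#'
#' Reads and validates the documented CSV schema
#' `embryo_id,cell_id,x_um,y_um,diameter_um,p63,dlc,brdu,condition`.
#' Row order is preserved; flags are normalized to logicals; errors report
#' the offending column and file line.
#'
#' @param path Path to a CSV file.
#' @return A validated cell table (data.frame).
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) {
    stop_ionopattern("schema_error", "file not found: %s", path)
  }
  raw <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  check_columns(names(raw), cell_table_columns, path)
  if (nrow(raw) == 0L) return(empty_cell_table())
  out <- data.frame(
    embryo_id = raw$embryo_id, cell_id = raw$cell_id,
    x_um = parse_num(raw$x_um, "x_um", path),
    y_um = parse_num(raw$y_um, "y_um", path),
    diameter_um = parse_num(raw$diameter_um, "diameter_um", path),
    p63 = parse_flag(raw$p63, "p63", path),
    dlc = parse_flag(raw$dlc, "dlc", path),
    brdu = parse_flag(raw$brdu, "brdu", path),
    condition = raw$condition, stringsAsFactors = FALSE)
  if (any(out$diameter_um <= 0)) {
    line <- which(out$diameter_um <= 0)[1]
    stop_ionopattern("schema_error",
                     "%s line %d: diameter_um must be > 0", path, line + 1L)
  }
  dup <- which(duplicated(out[c("embryo_id", "cell_id")]))
  if (length(dup) > 0L) {
    stop_ionopattern("schema_error",
                     "%s line %d: duplicate (embryo_id, cell_id) = (%s, %s)",
                     path, dup[1] + 1L, out$embryo_id[dup[1]],
                     out$cell_id[dup[1]])
  }
  out
}

#' Write a cell table
#' @param cells Cell table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  stopifnot(is.data.frame(cells))
  out <- cells[cell_table_columns]
  for (fl in c("p63", "dlc", "brdu")) out[[fl]] <- as.integer(out[[fl]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an embryo geometry table
#' @param path Path to a CSV with columns
#'   `embryo_id,cx_um,cy_um,radius_um,sector_center_rad,sector_halfwidth_rad,area_um2`.
#' @return A validated geometry table (data.frame).
#' @export
read_geometry_table <- function(path) {
  if (!file.exists(path)) {
    stop_ionopattern("schema_error", "file not found: %s", path)
  }
  raw <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  check_columns(names(raw), geometry_table_columns, path)
  if (nrow(raw) == 0L) return(geometry_table(list()))
  out <- data.frame(embryo_id = raw$embryo_id, stringsAsFactors = FALSE)
  for (col in setdiff(geometry_table_columns, "embryo_id")) {
    out[[col]] <- parse_num(raw[[col]], col, path)
  }
  if (anyDuplicated(out$embryo_id)) {
    stop_ionopattern("schema_error", "%s: duplicate embryo_id", path)
  }
  # validates radii/halfwidths via the geometry constructor
  for (i in seq_len(nrow(out))) geometry_from_row(out[i, ])
  out
}

#' Write an embryo geometry table
#' @param geometry Geometry table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_geometry_table <- function(geometry, path) {
  stopifnot(is.data.frame(geometry))
  write.csv(geometry[geometry_table_columns], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

# ---- pipeline configuration ------------------------------------------------

#' Assemble a pipeline configuration
#'
#' Bundles the cohort configuration with the analysis parameters and the
#' comparison design. Round-trips losslessly through JSON via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param cohort A [cohort_config()].
#' @param central_fraction,pair_threshold Analysis parameters (see
#'   [summarize_cohort()]).
#' @param reference Reference condition for [compare_conditions()];
#'   defaults to the first preset.
#' @param tests Test conditions; default all non-reference presets.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            central_fraction = 0.40, pair_threshold = 1.25,
                            reference = NULL, tests = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  nms <- names(cohort$presets)
  reference <- reference %||% nms[1]
  tests <- tests %||% setdiff(nms, reference)
  if (!reference %in% nms || !all(tests %in% nms)) {
    stop_ionopattern("invalid_config",
                     "reference/tests must name configured presets")
  }
  structure(list(cohort = cohort, central_fraction = central_fraction,
                 pair_threshold = pair_threshold, reference = reference,
                 tests = tests), class = "pipeline_config")
}

pipeline_config_to_list <- function(config) {
  g <- config$cohort$geometry
  list(
    cohort = list(
      presets = lapply(unname(config$cohort$presets), function(p) {
        unclass(p)
      }),
      n_embryos_per_condition = config$cohort$n_embryos_per_condition,
      seed = config$cohort$seed,
      geometry = list(radius = g$radius, sector_center = g$sector_center,
                      sector_halfwidth = g$sector_halfwidth,
                      centroid = g$centroid)),
    central_fraction = config$central_fraction,
    pair_threshold = config$pair_threshold,
    reference = config$reference,
    tests = as.list(config$tests))
}

#' Write a pipeline configuration as JSON
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(pipeline_config_to_list(config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys anywhere in the document are rejected, so configuration
#' typos fail loudly instead of silently using defaults.
#'
#' @param path Path to a JSON file written by [write_pipeline_config()] (or
#'   authored by hand against the same schema).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_ionopattern("invalid_config", "file not found: %s", path)
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  reject_unknown <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0L) {
      stop_ionopattern("invalid_config", "unknown key(s) in %s: %s",
                       where, paste(extra, collapse = ", "))
    }
  }
  reject_unknown(doc, c("cohort", "central_fraction", "pair_threshold",
                        "reference", "tests"), "config")
  reject_unknown(doc$cohort, c("presets", "n_embryos_per_condition", "seed",
                               "geometry"), "cohort")
  reject_unknown(doc$cohort$geometry,
                 c("radius", "sector_center", "sector_halfwidth", "centroid"),
                 "geometry")
  preset_fields <- names(formals(condition_preset))
  presets <- lapply(doc$cohort$presets, function(p) {
    reject_unknown(p, preset_fields, sprintf("preset '%s'", p$name %||% "?"))
    do.call(condition_preset, p)
  })
  g <- doc$cohort$geometry
  geometry <- make_geometry(radius = g$radius,
                            sector_center = g$sector_center,
                            sector_halfwidth = g$sector_halfwidth,
                            centroid = unlist(g$centroid))
  cohort <- cohort_config(presets = presets,
                          n_embryos_per_condition = doc$cohort$n_embryos_per_condition,
                          seed = doc$cohort$seed, geometry = geometry)
  pipeline_config(cohort = cohort,
                  central_fraction = doc$central_fraction,
                  pair_threshold = doc$pair_threshold,
                  reference = doc$reference,
                  tests = unlist(doc$tests))
}

# 31-bit multiplicative string hash; manifest fingerprinting only (not
# cryptographic). Exact in doubles: intermediates stay below 2^53.
string_hash32 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
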