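#' Read species occurrence records
#'
#' Reads long-format presence records — one row per (taxon, species, grid
#' cell) — from a comma-separated file with a header. Duplicated
#' (species, cell) pairs within a taxon are collapsed with a warning; the
#' resulting table is the canonical occurrence input for all downstream
#' stages.
#'
#' @param path Path to a CSV file with columns `taxon`, `species_id`,
#'   `cell_id`.
#' @return A tibble with columns `taxon`, `species_id`, `cell_id`, one row
#'   per presence.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) {
    ct_abort(sprintf("occurrence file not found: %s", path), "coretrans_io_error")
  }
  occ <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(occ) == 0) {
    ct_abort("occurrence file is empty", "coretrans_empty_input")
  }
  stopifnot_cols(occ, c("taxon", "species_id", "cell_id"), "occurrence table")
  occ <- dplyr::select(occ, "taxon", "species_id", "cell_id")
  validate_occurrences(occ)
}

#' Validate (and de-duplicate) an occurrence table
#'
#' @param occ A data frame with columns `taxon`, `species_id`, `cell_id`.
#' @return The validated tibble, duplicates collapsed.
#' @export
validate_occurrences <- function(occ) {
  stopifnot_cols(occ, c("taxon", "species_id", "cell_id"), "occurrence table")
  occ <- as_tibble(occ)
  n0 <- nrow(occ)
  if (n0 == 0) ct_abort("occurrence table has no rows", "coretrans_empty_input")
  occ <- distinct(occ, .data$taxon, .data$species_id, .data$cell_id)
  if (nrow(occ) < n0) {
    warn(sprintf("collapsed %d duplicated presence record(s)", n0 - nrow(occ)))
  }
  inform(sprintf(
    "occurrences: %d presences, %d species, %d cells, %d taxon/taxa",
    nrow(occ), n_distinct(occ$species_id), n_distinct(occ$cell_id),
    n_distinct(occ$taxon)
  ))
  occ
}

#' Read a regular-grid geometry table
#'
#' @param path Path to a CSV with columns `cell_id`, `row`, `col` and
#'   optionally `lon`, `lat`, `area_km2`.
#' @param resolution_km Grid resolution in km; used to fill a missing
#'   `area_km2` column as `resolution_km^2` and stored as an attribute.
#' @return A tibble with columns `cell_id`, `row`, `col`, `lon`, `lat`,
#'   `area_km2` and attribute `resolution_km`.
#' @export
read_grid <- function(path, resolution_km = 111) {
  if (!file.exists(path)) {
    ct_abort(sprintf("grid file not found: %s", path), "coretrans_io_error")
  }
  grid <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot_cols(grid, c("cell_id", "row", "col"), "grid table")
  grid$cell_id <- as.character(grid$cell_id)
  validate_grid(grid, resolution_km = resolution_km)
}

#' Validate a grid geometry table
#'
#' @inheritParams read_grid
#' @param grid Data frame with at least `cell_id`, `row`, `col`.
#' @return Validated tibble (see [read_grid()]).
#' @export
validate_grid <- function(grid, resolution_km = 111) {
  stopifnot_cols(grid, c("cell_id", "row", "col"), "grid table")
  grid <- as_tibble(grid)
  if (anyDuplicated(grid$cell_id)) {
    ct_abort("duplicate cell_id in grid table", "coretrans_validation_error")
  }
  if (anyDuplicated(grid[, c("row", "col")])) {
    ct_abort("duplicate (row, col) in grid table", "coretrans_validation_error")
  }
  if (!("lon" %in% names(grid))) grid$lon <- as.numeric(grid$col)
  if (!("lat" %in% names(grid))) grid$lat <- as.numeric(grid$row)
  if (!("area_km2" %in% names(grid))) grid$area_km2 <- resolution_km^2
  if (any(grid$area_km2 <= 0)) {
    ct_abort("grid cell areas must be positive", "coretrans_validation_error")
  }
  attr(grid, "resolution_km") <- resolution_km
  grid
}

#' Aggregate per-pixel environmental values to grid cells
#'
#' Averages finer-resolution pixel values within each grid cell, matching the
#' usual raster-to-grid alignment step. Cells present in the grid but without
#' any contributing pixel get `NA` and are flagged with a message.
#'
#' @param pixels A data frame with columns `cell_id`, `variable`, `value`
#'   (one row per contributing pixel).
#' @param grid A grid table from [read_grid()].
#' @return A wide tibble: one row per grid cell, one column per variable.
#' @export
aggregate_env <- function(pixels, grid) {
  stopifnot_cols(pixels, c("cell_id", "variable", "value"), "pixel table")
  pixels <- as_tibble(pixels)
  unknown <- setdiff(unique(pixels$cell_id), grid$cell_id)
  if (length(unknown) > 0) {
    ct_abort(sprintf("pixel table references unknown cell(s): %s",
                     paste(head(unknown, 5), collapse = ", ")),
             "coretrans_validation_error")
  }
  agg <- pixels |>
    group_by(.data$cell_id, .data$variable) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  out <- left_join(tibble(cell_id = grid$cell_id), agg, by = "cell_id")
  n_missing <- sum(!complete.cases(out))
  if (n_missing > 0) {
    inform(sprintf("aggregate_env: %d cell(s) without pixels -> NA", n_missing))
  }
  out
}

#' Write a sector map as GeoJSON and CSV
#'
#' Writes the sector assignment as (1) a GeoJSON FeatureCollection of square
#' cell polygons centred on each cell's (lon, lat) and (2) a flat CSV twin
#' whose re-read reproduces the assignment exactly. The polygon side is the
#' grid resolution converted to degrees with the constant 1 degree = 111 km;
#' this conversion is for display only, no analysis depends on it.
#'
#' @param assignment A sector assignment (see [general_sectors()]) or any
#'   data frame with columns `cell_id`, `taxon`, `sector`.
#' @param grid Grid table covering every assigned cell.
#' @param path Output path; `.geojson` and `.csv` files are written with this
#'   stem.
#' @param bioregions Optional tibble `cell_id`, `module` adding a `bioregion`
#'   property.
#' @return Invisibly, a list with the two file paths.
#' @export
write_sector_map <- function(assignment, grid, path, bioregions = NULL) {
  cells <- if (inherits(assignment, "ct_sectors")) assignment$cells else as_tibble(assignment)
  stopifnot_cols(cells, c("cell_id", "taxon", "sector"), "sector assignment")
  missing_cells <- setdiff(cells$cell_id, grid$cell_id)
  if (length(missing_cells) > 0) {
    ct_abort(sprintf("assigned cell(s) absent from grid: %s",
                     paste(head(missing_cells, 5), collapse = ", ")),
             "coretrans_validation_error")
  }
  if (nrow(cells) == 0) warn("empty sector assignment: writing empty collection")
  if (!is.null(bioregions)) {
    cells <- left_join(cells, dplyr::select(bioregions, "cell_id", bioregion = "module"),
                       by = "cell_id")
  } else {
    cells$bioregion <- NA_integer_
  }
  geo <- left_join(cells, dplyr::select(grid, "cell_id", "lon", "lat"), by = "cell_id")
  half <- (attr(grid, "resolution_km") %||% 111) / 111 / 2  # km -> degrees
  features <- purrr::pmap(geo, function(cell_id, taxon, sector, bioregion, lon, lat, ...) {
    ring <- list(
      c(lon - half, lat - half), c(lon + half, lat - half),
      c(lon + half, lat + half), c(lon - half, lat + half),
      c(lon - half, lat - half)
    )
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(cell_id = cell_id, taxon = taxon,
                        bioregion = bioregion, sector = sector)
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  stem <- sub("\\.(geojson|csv|json)$", "", path)
  geojson_path <- paste0(stem, ".geojson")
  csv_path <- paste0(stem, ".csv")
  jsonlite::write_json(fc, geojson_path, auto_unbox = TRUE, digits = NA)
  readr::write_csv(dplyr::select(cells, "cell_id", "taxon", "bioregion", "sector"),
                   csv_path)
  invisible(list(geojson = geojson_path, csv = csv_path))
}
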