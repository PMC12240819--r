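#' Configuration for a synthetic biogeographical landscape
#'
#' Builds the parameter list consumed by [generate_landscape()]. The defaults
#' define the package's reference landscape: a 60x60 lattice tiled by four
#' contiguous rectangular regions, each with 200 species whose range centroids
#' concentrate around a regional hotspot, right-skewed (log-normal) range
#' sizes that grow toward the region boundary, and permeable borders that let
#' large-ranged boundary species spill into neighbouring regions.
#'
#' @param grid_rows,grid_cols Lattice dimensions (cells).
#' @param n_regions Number of regions; regions tile the lattice as contiguous
#'   rectangular blocks.
#' @param species_per_region Species in each regional pool; a scalar or a
#'   vector of length `n_regions` (regional pools of different sizes).
#' @param range_size_frac Median range size of a hotspot-centred species as
#'   a fraction of its region's area; sets the log-normal location when
#'   `range_size_meanlog` is `NULL`. Sized so that regional species pools
#'   overlap broadly within their region (cohesive bioregions) while leaving
#'   a core-to-boundary range-size gradient.
#' @param range_size_meanlog,range_size_sdlog Log-normal parameters of the
#'   target range size, in cells, for a species whose centroid sits on the
#'   hotspot; `range_size_meanlog = NULL` (default) derives the location
#'   from `range_size_frac` and the region area.
#' @param range_size_gradient Added to `range_size_meanlog` in proportion to
#'   the centroid's normalised distance from the hotspot (0 at the hotspot,
#'   1 at the farthest cell of the region), so boundary species are the most
#'   widespread.
#' @param hotspot_concentration Decay rate (per cell of Chebyshev distance)
#'   of the range-centroid density away from the regional hotspot; 0 gives
#'   uniform centroids.
#' @param permeability Probability in `[0, 1]` that a species whose range
#'   touches a region border spills across it; modulated by a logistic
#'   preference for large-ranged species.
#' @param spill_depth Maximum penetration (cells) of a spilled range into the
#'   neighbouring region.
#' @param env_gradient Named list of environmental variables. Each entry is a
#'   list with `means` (per-region means, recycled if length 1), `slope`
#'   (change over the normalised hotspot distance) and `sd` (cell-level
#'   noise).
#' @param taxon Label attached to the generated occurrence records.
#' @param resolution_km Grid resolution, km (metadata only).
#' @param seed Integer seed; the whole landscape is reproducible from it.
#' @return A `ct_landscape_config` list.
#' @export
landscape_config <- function(grid_rows = 60, grid_cols = 60,
                             n_regions = 4, species_per_region = 200,
                             range_size_frac = 0.12,
                             range_size_meanlog = NULL,
                             range_size_sdlog = 0.6,
                             range_size_gradient = 1.8,
                             hotspot_concentration = 0.4,
                             permeability = 0.25,
                             spill_depth = 4,
                             env_gradient = list(
                               temperature = list(means = NULL, slope = 6, sd = 1),
                               precipitation = list(means = NULL, slope = -300, sd = 60)
                             ),
                             taxon = "synthetic",
                             resolution_km = 111,
                             seed = 1L) {
  if (n_regions < 1) ct_abort("n_regions must be >= 1", "coretrans_config_error")
  if (!(length(species_per_region) %in% c(1, n_regions))) {
    ct_abort("species_per_region must be a scalar or one value per region",
             "coretrans_config_error")
  }
  species_per_region <- rep_len(species_per_region, n_regions)
  if (any(species_per_region < 1) || sum(species_per_region) == 0) {
    ct_abort("species_per_region x n_regions must be positive", "coretrans_config_error")
  }
  if (permeability < 0 || permeability > 1) {
    ct_abort("permeability must be in [0, 1]", "coretrans_config_error")
  }
  if (hotspot_concentration < 0) {
    ct_abort("hotspot_concentration must be non-negative", "coretrans_config_error")
  }
  # default per-region environmental means, spread across a plausible range
  if (is.null(env_gradient$temperature$means)) {
    env_gradient$temperature$means <- seq(8, 26, length.out = n_regions)
  }
  if (!is.null(env_gradient$precipitation) && is.null(env_gradient$precipitation$means)) {
    env_gradient$precipitation$means <- seq(1600, 400, length.out = n_regions)
  }
  structure(
    list(grid_rows = grid_rows, grid_cols = grid_cols, n_regions = n_regions,
         species_per_region = species_per_region,
         range_size_frac = range_size_frac,
         range_size_meanlog = range_size_meanlog,
         range_size_sdlog = range_size_sdlog,
         range_size_gradient = range_size_gradient,
         hotspot_concentration = hotspot_concentration,
         permeability = permeability, spill_depth = spill_depth,
         env_gradient = env_gradient, taxon = taxon,
         resolution_km = resolution_km, seed = as.integer(seed)),
    class = "ct_landscape_config"
  )
}

# Tile n_regions as an r1 x r2 block layout, r1 the largest divisor <= sqrt(n)
region_layout <- function(n_regions) {
  r1 <- floor(sqrt(n_regions))
  while (n_regions %% r1 != 0) r1 <- r1 - 1
  c(r1, n_regions / r1)
}

# Split `len` positions into `parts` contiguous near-equal bands; returns the
# band index per position.
band_index <- function(len, parts) {
  ceiling(seq_len(len) / len * parts)
}

#' Generate a synthetic landscape with known ground truth
#'
#' Draws a full dataset — occurrences, grid, environmental table — together
#' with the truth used to validate every downstream stage: the region of each
#' cell, its Chebyshev distance to the regional hotspot and the within-region
#' quantile of that distance (`core_rank`), plus each species' origin region
#' and realised range size.
#'
#' Species ranges are Chebyshev discs around a centroid sampled with density
#' `exp(-hotspot_concentration * distance)` from the hotspot; the disc is
#' clipped to the origin region unless the species spills, in which case it
#' may extend up to `spill_depth` cells into neighbouring regions. Spilling
#' species are drawn preferentially among large-ranged species (logistic in
#' log range size), so boundary biotas are dominated by widespread,
#' low-endemicity species.
#'
#' @param config A [landscape_config()].
#' @return A `ct_landscape` list with tibbles `occurrences`, `grid`, `env`,
#'   `truth_cells`, `truth_species`, and the `config`.
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "ct_landscape_config"))
  withr::with_seed(config$seed, generate_landscape_impl(config))
}

generate_landscape_impl <- function(config) {
  nr <- config$grid_rows; nc <- config$grid_cols
  layout <- region_layout(config$n_regions)
  row_band <- band_index(nr, layout[1])
  col_band <- band_index(nc, layout[2])

  grid <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc)) |>
    mutate(cell_id = sprintf("c%03d-%03d", .data$row, .data$col),
           lon = .data$col - 0.5, lat = .data$row - 0.5,
           area_km2 = config$resolution_km^2,
           region_id = (row_band[.data$row] - 1L) * layout[2] + col_band[.data$col]) |>
    dplyr::select("cell_id", "row", "col", "lon", "lat", "area_km2", "region_id")

  # region bounding boxes and hotspots (block centres)
  regions <- grid |>
    group_by(.data$region_id) |>
    summarise(rmin = min(.data$row), rmax = max(.data$row),
              cmin = min(.data$col), cmax = max(.data$col), .groups = "drop") |>
    mutate(hot_row = floor((.data$rmin + .data$rmax) / 2),
           hot_col = floor((.data$cmin + .data$cmax) / 2))

  grid <- left_join(grid, regions, by = "region_id") |>
    mutate(dist_hotspot = pmax(abs(.data$row - .data$hot_row),
                               abs(.data$col - .data$hot_col)))

  truth_cells <- grid |>
    group_by(.data$region_id) |>
    mutate(core_rank = rank(.data$dist_hotspot, ties.method = "average") / n()) |>
    ungroup() |>
    dplyr::select("cell_id", region_id = "region_id",
                  distance_to_hotspot = "dist_hotspot", "core_rank")

  species_tbl <- vector("list", config$n_regions)
  occ_tbl <- vector("list", config$n_regions)
  for (rg in seq_len(config$n_regions)) {
    reg <- regions[regions$region_id == rg, ]
    cells_r <- grid[grid$region_id == rg, ]
    dmax <- max(cells_r$dist_hotspot)
    w <- exp(-config$hotspot_concentration * cells_r$dist_hotspot)
    meanlog_r <- config$range_size_meanlog %||%
      log(config$range_size_frac * nrow(cells_r))
    mid_meanlog <- meanlog_r + 0.5 * config$range_size_gradient

    n_spp <- config$species_per_region[rg]
    sp_rows <- vector("list", n_spp)
    oc_rows <- vector("list", n_spp)
    for (j in seq_len(n_spp)) {
      centroid <- cells_r[sample.int(nrow(cells_r), 1, prob = w), ]
      dnorm_c <- if (dmax > 0) centroid$dist_hotspot / dmax else 0
      size <- rlnorm(1, meanlog_r + config$range_size_gradient * dnorm_c,
                     config$range_size_sdlog)
      radius <- max(0L, as.integer(round((sqrt(size) - 1) / 2)))

      disc <- grid[abs(grid$row - centroid$row) <= radius &
                   abs(grid$col - centroid$col) <= radius, ]
      touches_border <- any(disc$region_id != rg) ||
        centroid$row - radius < reg$rmin || centroid$row + radius > reg$rmax ||
        centroid$col - radius < reg$cmin || centroid$col + radius > reg$cmax
      pref <- stats::plogis(1.5 * (log(size) - mid_meanlog) / config$range_size_sdlog)
      spills <- touches_border &&
        runif(1) < min(1, 2 * config$permeability * pref)
      if (spills) {
        # clip to origin region plus a spill_depth buffer into neighbours
        drow <- pmax(0, reg$rmin - disc$row, disc$row - reg$rmax)
        dcol <- pmax(0, reg$cmin - disc$col, disc$col - reg$cmax)
        disc <- disc[pmax(drow, dcol) <= config$spill_depth, ]
      } else {
        disc <- disc[disc$region_id == rg, ]
      }
      sid <- sprintf("s%d-%03d", rg, j)
      sp_rows[[j]] <- tibble(species_id = sid, origin_region = rg,
                             true_range_size = nrow(disc),
                             centroid_cell = centroid$cell_id,
                             centroid_distance = centroid$dist_hotspot,
                             spilled = spills)
      oc_rows[[j]] <- tibble(species_id = sid, cell_id = disc$cell_id)
    }
    species_tbl[[rg]] <- bind_rows(sp_rows)
    occ_tbl[[rg]] <- bind_rows(oc_rows)
  }
  truth_species <- bind_rows(species_tbl)
  occurrences <- bind_rows(occ_tbl) |>
    mutate(taxon = config$taxon) |>
    dplyr::select("taxon", "species_id", "cell_id")

  # environmental covariates: region mean + radial trend + noise
  cell_dnorm <- grid |>
    group_by(.data$region_id) |>
    mutate(dnorm = if (max(.data$dist_hotspot) > 0)
      .data$dist_hotspot / max(.data$dist_hotspot) else 0) |>
    ungroup()
  env <- tibble(cell_id = grid$cell_id)
  for (var in names(config$env_gradient)) {
    g <- config$env_gradient[[var]]
    means <- rep_len(g$means, config$n_regions)
    env[[var]] <- means[cell_dnorm$region_id] +
      g$slope * cell_dnorm$dnorm + rnorm(nrow(grid), 0, g$sd)
  }

  grid_out <- validate_grid(
    dplyr::select(grid, "cell_id", "row", "col", "lon", "lat", "area_km2"),
    resolution_km = config$resolution_km
  )
  structure(
    list(occurrences = occurrences, grid = grid_out, env = env,
         truth_cells = truth_cells, truth_species = truth_species,
         config = config),
    class = "ct_landscape"
  )
}

#' @export
print.ct_landscape <- function(x, ...) {
  cat(sprintf(
    "<ct_landscape> %d x %d grid, %d regions, %d species, %d presences (seed %d)\n",
    x$config$grid_rows, x$config$grid_cols, x$config$n_regions,
    nrow(x$truth_species), nrow(x$occurrences), x$config$seed
  ))
  invisible(x)
}

#' Discretize ground-truth core ranks into layers
#'
#' Equal-frequency binning of `core_rank` within each region, giving the
#' reference "layer" (1 = most core) each cell should fall into; used for
#' recovery tests against inferred sectors. Ties at bin edges are broken by
#' `cell_id` order, so the output is deterministic.
#'
#' @param truth_cells The `truth_cells` tibble of a [generate_landscape()].
#' @param n_layers Number of layers (>= 2).
#' @return `truth_cells` with an integer `layer` column.
#' @export
truth_sector_layers <- function(truth_cells, n_layers) {
  if (!is_count(n_layers) || n_layers < 2) {
    ct_abort("n_layers must be an integer >= 2", "coretrans_config_error")
  }
  out <- truth_cells |>
    group_by(.data$region_id) |>
    arrange(.data$core_rank, .data$cell_id, .by_group = TRUE) |>
    mutate(layer = ceiling(row_number() / n() * min(n_layers, n()))) |>
    ungroup() |>
    arrange(.data$cell_id)
  small <- truth_cells |>
    count(.data$region_id) |>
    filter(.data$n < n_layers)
  if (nrow(small) > 0) {
    warn(sprintf("%d region(s) have fewer cells than n_layers; fewer layers used",
                 nrow(small)))
  }
  out
}

#' Simulate cell aspect vectors from planted archetypes
#'
#' A test-bed generator for the sector clustering: draws cells for several
#' taxa from a shared set of well-separated archetype centroids in the
#' four-aspect space, plus isotropic Gaussian noise. Centroids sit at the
#' vertices of a regular simplex (every pairwise distance equals `spacing`,
#' so merging any two archetypes is equally costly and the GoF curve has a
#' sharp elbow at the true number), randomly rotated in the full 4-D space
#' so every aspect dimension carries signal.
#'
#' @param n_taxa Number of taxa.
#' @param n_archetypes Number of planted archetypes (2 to 5; a regular
#'   simplex in 4-D has at most 5 vertices).
#' @param cells_per_taxon Cells drawn per taxon, cycled across archetypes.
#' @param spacing Minimum distance between archetype centroids.
#' @param noise_sd Isotropic noise standard deviation.
#' @param seed Integer seed.
#' @return A tibble shaped like a cell-aspect table (`cell_id`, `taxon`,
#'   `relative_richness`, `biota_overlap`, `endemicity`,
#'   `relative_occupancy`, `valid`) plus the true `archetype`.
#' @export
simulate_archetype_aspects <- function(n_taxa = 3, n_archetypes = 5,
                                       cells_per_taxon = 240,
                                       spacing = 8, noise_sd = 1, seed = 1L) {
  stopifnot(n_archetypes >= 2, n_archetypes <= 5)
  withr::with_seed(as.integer(seed), {
    # centred unit vectors of R^G give a regular simplex with side sqrt(2)
    simplex <- diag(n_archetypes) - 1 / n_archetypes
    coords <- matrix(0, n_archetypes, 4)
    coords[, seq_len(n_archetypes - 1)] <-
      simplex %*% qr.Q(qr(t(simplex)))[, seq_len(n_archetypes - 1)]
    rot <- qr.Q(qr(matrix(rnorm(16), 4)))
    centroids <- coords %*% rot * spacing / sqrt(2)
    purrr::map_dfr(seq_len(n_taxa), function(tx) {
      arch <- rep_len(seq_len(n_archetypes), cells_per_taxon)
      noise <- matrix(rnorm(cells_per_taxon * 4, 0, noise_sd), ncol = 4)
      vals <- centroids[arch, , drop = FALSE] + noise
      tibble(
        cell_id = sprintf("t%d-%04d", tx, seq_len(cells_per_taxon)),
        taxon = sprintf("taxon%d", tx),
        archetype = arch,
        relative_richness = vals[, 1],
        biota_overlap = vals[, 2],
        endemicity = vals[, 3],
        relative_occupancy = vals[, 4],
        valid = TRUE
      )
    })
  })
}
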