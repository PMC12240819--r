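#' Pool presences into a sector-by-species matrix
#'
#' Builds, for one region and one species group, the site-by-species
#' incidence matrix whose sites are the region's sectors (a species is
#' present at a site when it occurs in at least one cell of that sector).
#' Groups: `"characteristic"` uses the region's characteristic presences;
#' `"non-characteristic"` uses non-characteristic presences, restricted to
#' one origin module via `origin`.
#'
#' @param classification Presence classification from
#'   [classify_presences()].
#' @param assignment A `ct_sectors` or data frame `cell_id`, `sector`.
#' @param region Module id of the region (its cells' module).
#' @param group `"characteristic"` or `"non-characteristic"`.
#' @param origin Origin module of the non-characteristic species (required
#'   for that group).
#' @return A logical matrix (sectors x species), or `NULL` with a message
#'   when fewer than two sectors hold presences of the group.
#' @export
sector_site_matrix <- function(classification, assignment, region,
                               group = c("characteristic", "non-characteristic"),
                               origin = NULL) {
  group <- match.arg(group)
  cells <- if (inherits(assignment, "ct_sectors")) assignment$cells else as_tibble(assignment)
  pres <- classification |>
    filter(.data$cell_module == region) |>
    inner_join(dplyr::select(cells, "cell_id", "sector"), by = "cell_id")
  pres <- if (group == "characteristic") {
    filter(pres, .data$characteristic)
  } else {
    if (is.null(origin)) {
      ct_abort("origin module required for the non-characteristic group",
               "coretrans_validation_error")
    }
    filter(pres, !.data$characteristic, .data$origin_module == origin)
  }
  if (nrow(pres) == 0 || n_distinct(pres$sector) < 2) {
    inform(sprintf(
      "sector_site_matrix: region %s, group %s%s skipped (fewer than 2 occupied sectors)",
      region, group, if (is.null(origin)) "" else paste0(" from ", origin)))
    return(NULL)
  }
  inc <- distinct(pres, .data$sector, .data$species_id)
  sectors <- sort(unique(inc$sector))
  species <- sort(unique(inc$species_id))
  m <- matrix(FALSE, length(sectors), length(species),
              dimnames = list(as.character(sectors), species))
  m[cbind(match(inc$sector, sectors), match(inc$species_id, species))] <- TRUE
  m
}

#' Multi-site Sorensen dissimilarity partitioned into turnover and nestedness
#'
#' Computes the multi-site Sorensen dissimilarity `beta_SOR` and its
#' partition into the spatial-turnover component `beta_SIM` (Simpson-based)
#' and the nestedness-resultant component `beta_SNE = beta_SOR - beta_SIM`,
#' with the nestedness ratio `beta_SNE / beta_SOR`. With `S_i` the richness
#' of site i, `S_T` the pooled richness and `b_ij` the number of species
#' present in site i but not j (pairwise, unordered sums):
#' \deqn{\beta_{SIM} = \frac{\sum \min(b_{ij}, b_{ji})}{\sum_i S_i - S_T + \sum \min(b_{ij}, b_{ji})}}
#' \deqn{\beta_{SOR} = \frac{\sum \min + \sum \max}{2(\sum_i S_i - S_T) + \sum \min + \sum \max}}
#'
#' @param sites Logical/0-1 site-by-species matrix (>= 2 sites). Species
#'   absent everywhere are dropped.
#' @return A tibble: `beta_sor`, `beta_sim`, `beta_sne`,
#'   `nestedness_ratio` (`NA` when `beta_sor = 0`, flagged by `degenerate`),
#'   `n_sites`, `n_species`.
#' @export
multisite_sorensen_partition <- function(sites) {
  m <- as.matrix(sites) > 0
  if (nrow(m) < 2) ct_abort("need >= 2 sites", "coretrans_validation_error")
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (any(rowSums(m) == 0)) {
    ct_abort("every site must hold at least one species", "coretrans_validation_error")
  }
  Si <- rowSums(m)
  ST <- ncol(m)
  shared <- m %*% t(m)                       # a_ij
  bmat <- matrix(Si, nrow(m), nrow(m)) - shared  # b_ij = S_i - a_ij
  pairs <- which(upper.tri(bmat), arr.ind = TRUE)
  bij <- bmat[pairs]
  bji <- t(bmat)[pairs]
  sum_min <- sum(pmin(bij, bji))
  sum_max <- sum(pmax(bij, bji))
  core <- sum(Si) - ST
  beta_sim <- if (sum_min + core > 0) sum_min / (core + sum_min) else 0
  denom <- 2 * core + sum_min + sum_max
  beta_sor <- if (denom > 0) (sum_min + sum_max) / denom else 0
  beta_sne <- beta_sor - beta_sim
  degenerate <- beta_sor == 0
  if (degenerate) inform("multisite_sorensen_partition: identical sites (beta_SOR = 0)")
  tibble(
    beta_sor = beta_sor, beta_sim = beta_sim, beta_sne = beta_sne,
    nestedness_ratio = if (degenerate) NA_real_ else beta_sne / beta_sor,
    degenerate = degenerate, n_sites = nrow(m), n_species = ST
  )
}

#' Beta-diversity partition for every region and species group
#'
#' For each region: the characteristic-species partition across its sectors,
#' plus one partition per origin of its non-characteristic species.
#'
#' @inheritParams sector_site_matrix
#' @return A tibble with one row per (region, group, origin) analysis.
#' @export
region_beta_partition <- function(classification, assignment) {
  regions <- sort(unique(classification$cell_module[!classification$excluded]))
  purrr::map_dfr(regions, function(rg) {
    out <- list()
    m <- sector_site_matrix(classification, assignment, rg, "characteristic")
    if (!is.null(m)) {
      out <- c(out, list(mutate(multisite_sorensen_partition(m),
                                module = rg, group = "characteristic",
                                origin = NA_integer_)))
    }
    origins <- classification |>
      filter(.data$cell_module == rg, !.data$characteristic) |>
      pull(.data$origin_module) |>
      unique() |>
      sort()
    for (og in origins) {
      m <- sector_site_matrix(classification, assignment, rg,
                              "non-characteristic", origin = og)
      if (!is.null(m)) {
        out <- c(out, list(mutate(multisite_sorensen_partition(m),
                                  module = rg, group = "non-characteristic",
                                  origin = og)))
      }
    }
    bind_rows(out)
  })
}

#' Summarise nestedness dominance across regions
#'
#' Fraction of analyses, per species group, whose dissimilarity is mostly
#' nestedness (`nestedness_ratio > 0.5`), with distribution summaries.
#'
#' @param results Output of [region_beta_partition()] (or rows of several
#'   taxa bound together).
#' @return A tibble per group: `n`, `fraction_nested`, `median_ratio`,
#'   `mean_ratio`.
#' @export
nestedness_summary <- function(results) {
  if (nrow(results) == 0) ct_abort("no beta-partition results", "coretrans_empty_input")
  results |>
    filter(!is.na(.data$nestedness_ratio)) |>
    group_by(.data$group) |>
    summarise(
      n = n(),
      fraction_nested = mean(.data$nestedness_ratio > 0.5),
      median_ratio = median(.data$nestedness_ratio),
      mean_ratio = mean(.data$nestedness_ratio),
      .groups = "drop"
    )
}
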