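#' Decompose cell richness into pool size and sorting components
#'
#' For every cell of a retained region: observed richness `S` (all
#' presences), the regional pool size (total characteristic species of the
#' cell's region), and the centred characteristic and non-characteristic
#' richness (observed minus the region mean), which represent species
#' sorting within the region net of pool size.
#'
#' @param classification Presence classification from
#'   [classify_presences()].
#' @param partition A filtered `ct_partition`.
#' @return A tibble per cell: `cell_id`, `module`, `S`, `richness_char`,
#'   `richness_nonchar`, `pool_size`, `centred_char`, `centred_nonchar`,
#'   `region_size`.
#' @export
decompose_richness <- function(classification, partition) {
  retained <- partition$modules$module[partition$modules$retained]
  pool <- classification |>
    filter(.data$characteristic, .data$species_module %in% retained) |>
    group_by(module = .data$species_module) |>
    summarise(pool_size = n_distinct(.data$species_id), .groups = "drop")
  cells <- classification |>
    filter(.data$cell_module %in% retained) |>
    group_by(cell_id = .data$cell_id, module = .data$cell_module) |>
    summarise(S = n(),
              richness_char = sum(.data$characteristic),
              richness_nonchar = sum(!.data$characteristic),
              .groups = "drop")
  cells |>
    left_join(pool, by = "module") |>
    mutate(pool_size = dplyr::coalesce(.data$pool_size, 0L)) |>
    group_by(.data$module) |>
    mutate(centred_char = .data$richness_char - mean(.data$richness_char),
           centred_nonchar = .data$richness_nonchar - mean(.data$richness_nonchar),
           region_size = n()) |>
    ungroup()
}

#' Partition richness variance among pool size and sorting
#'
#' Least squares of `S` on pool size, centred characteristic richness and
#' centred non-characteristic richness, optionally weighted by the inverse
#' region size (weights normalised to sum to the number of cells). Each
#' variable's individual (non-shared) fraction is the drop in multiple R2
#' when it is removed from the saturated model; fractions are non-negative
#' by construction. Variables constant in the design (e.g. pool size with a
#' single region) get `NA` with a reason.
#'
#' @param decomposition Output of [decompose_richness()].
#' @param weighting `"inverse-region-size"` or `"none"`.
#' @return A list: `fractions` tibble (`term`, `fraction`, `reason`),
#'   `r2_full`, `r2_adjusted`, `n`, `weighting`.
#' @export
weighted_variance_partition <- function(decomposition,
                                        weighting = c("inverse-region-size", "none")) {
  weighting <- match.arg(weighting)
  dec <- as_tibble(decomposition)
  if (nrow(dec) < 10) ct_abort("need >= 10 cells", "coretrans_validation_error")
  w <- if (weighting == "inverse-region-size") 1 / dec$region_size else rep(1, nrow(dec))
  w <- w * nrow(dec) / sum(w)
  terms <- c("pool_size", "centred_char", "centred_nonchar")
  usable <- terms[purrr::map_lgl(terms, ~ ct_sd(dec[[.x]]) > 0)]

  r2_of <- function(vars) {
    if (length(vars) == 0 || ct_sd(dec$S) == 0) return(0)
    f <- as.formula(paste("S ~", paste(vars, collapse = " + ")))
    summary(lm(f, data = dec, weights = w))$r.squared
  }
  full <- lm(as.formula(paste("S ~", paste(usable, collapse = " + "))),
             data = dec, weights = w)
  r2_full <- r2_of(usable)
  r2_adj <- if (ct_sd(dec$S) == 0) 0 else summary(full)$adj.r.squared
  fractions <- purrr::map_dfr(terms, function(tm) {
    if (!(tm %in% usable)) {
      return(tibble(term = tm, fraction = NA_real_,
                    reason = "constant in design (collinear)"))
    }
    tibble(term = tm,
           fraction = r2_full - r2_of(setdiff(usable, tm)),
           reason = NA_character_)
  })
  list(fractions = fractions, r2_full = r2_full, r2_adjusted = r2_adj,
       n = nrow(dec), weighting = weighting)
}

#' Randomization test: is core richness higher than expected?
#'
#' For each region, compares the pooled characteristic richness of its core
#' cells with a null built by permuting the sector labels among the region's
#' cells (preserving per-sector cell counts). The default core is the
#' leading sectors — in the canonical core-to-transition order — that
#' together cover about 30 percent of the region's cells. The p-value uses
#' the add-one rule `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param assignment A `ct_sectors`.
#' @param classification Presence classification from
#'   [classify_presences()].
#' @param core_sectors Sector labels forming the core (default: chosen per
#'   region to cover ~30 percent of cells).
#' @param core_fraction Target core area fraction for the default rule.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return A tibble per region: `module`, `core_sectors` (list), `n_core`,
#'   `core_fraction`, `observed`, `null_mean`, `null_sd`, `p_value`,
#'   `degenerate`.
#' @export
core_richness_test <- function(assignment, classification,
                               core_sectors = NULL, core_fraction = 0.3,
                               n_perm = 100, seed = 1L) {
  stopifnot(inherits(assignment, "ct_sectors"))
  if (!is_count(n_perm) || n_perm < 1) {
    ct_abort("n_perm must be a positive integer", "coretrans_validation_error")
  }
  char <- filter(classification, .data$characteristic, !.data$excluded)
  cells <- assignment$cells |>
    inner_join(distinct(char, .data$cell_id, module = .data$cell_module),
               by = "cell_id")
  regions <- sort(unique(cells$module))
  seeds <- derive_seeds(seed, length(regions))
  purrr::map2_dfr(regions, seeds, function(rg, s) {
    reg_cells <- filter(cells, .data$module == rg)
    pres <- char |>
      filter(.data$cell_module == rg) |>
      inner_join(dplyr::select(reg_cells, "cell_id", "sector"), by = "cell_id")
    core <- core_sectors %||% {
      sizes <- reg_cells |> count(.data$sector) |> arrange(.data$sector)
      cum <- cumsum(sizes$n) / sum(sizes$n)
      sizes$sector[seq_len(which(cum >= core_fraction)[1])]
    }
    if (!any(core %in% reg_cells$sector)) {
      ct_abort(sprintf("core sector(s) absent from region %s", rg),
               "coretrans_validation_error")
    }
    is_core <- reg_cells$sector %in% core
    degenerate <- all(is_core)
    if (degenerate) {
      inform(sprintf("core_richness_test: core covers all cells of region %s", rg))
    }
    sp_by_cell <- split(pres$species_id, pres$cell_id)
    richness_of <- function(core_cells) {
      n_distinct(unlist(sp_by_cell[core_cells], use.names = FALSE))
    }
    observed <- richness_of(reg_cells$cell_id[is_core])
    null <- withr::with_seed(s, {
      purrr::map_int(seq_len(n_perm), function(i) {
        shuffled <- sample(reg_cells$cell_id)
        richness_of(shuffled[is_core])
      })
    })
    tibble(
      module = rg, core_sectors = list(sort(core)),
      n_core = sum(is_core), core_fraction = mean(is_core),
      observed = observed, null_mean = mean(null), null_sd = stats::sd(null),
      p_value = (1 + sum(null >= observed)) / (n_perm + 1),
      degenerate = degenerate
    )
  })
}
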