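#' Species-level cartography: relative occupancy and endemicity
#'
#' For every characteristic species of a retained module: the within-module
#' degree z-score `z_spp = (I_s - mean(I_s)) / sd(I_s)` (relative occupancy of
#' the species in its bioregion, mean and sd taken over the module's
#' characteristic species) and the endemicity fraction `C_endem = I_s / L_s`
#' (share of the species' range inside its bioregion; 1 = endemic). `I_s` is
#' the number of the species' links to cells of its own module and `L_s` its
#' total number of links.
#'
#' @param graph A `ct_bigraph`.
#' @param partition A filtered `ct_partition`.
#' @param sd_convention `"sample"` (n - 1 denominator, the default) or
#'   `"population"`.
#' @return A tibble: `species_id`, `module`, `I_s`, `L_s`, `z_spp`,
#'   `c_endem`.
#' @export
species_aspects <- function(graph, partition,
                            sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  retained <- partition$modules$module[partition$modules$retained]
  links <- link_modules(graph, partition)
  spp <- links |>
    group_by(species_id = .data$species_id, module = .data$species_module) |>
    summarise(I_s = sum(.data$cell_module == .data$species_module[1]),
              L_s = n(), .groups = "drop") |>
    filter(.data$module %in% retained)
  spp <- spp |>
    group_by(.data$module) |>
    mutate(sd_I = ct_sd(.data$I_s, sd_convention),
           z_spp = (.data$I_s - mean(.data$I_s)) / .data$sd_I) |>
    ungroup()
  if (any(!is.finite(spp$z_spp))) {
    ct_abort("z_spp undefined in a retained module; run filter_modules() first",
             "coretrans_internal_error")
  }
  spp |>
    mutate(c_endem = .data$I_s / .data$L_s) |>
    dplyr::select("species_id", "module", "I_s", "L_s", "z_spp", "c_endem")
}

#' Cell-level biodiversity aspects
#'
#' Computes, for every cell of a retained module, the four aspects used to
#' define biogeographical sectors:
#' * `relative_richness` — within-module z-score of the cell's
#'   characteristic richness, `(I_c - mean(I_c)) / sd(I_c)`;
#' * `biota_overlap` — `O_c / L_c`, the fraction of the cell's presences
#'   belonging to species of other modules (0 = no non-characteristic
#'   species; 0.4 = 40 percent non-characteristic);
#' * `endemicity` — median `C_endem` over the characteristic species present
#'   in the cell;
#' * `relative_occupancy` — median `z_spp` over the same species.
#'
#' Links to species of excluded modules still count in `O_c` (they are real
#' presences). Cells with no characteristic species get `valid = FALSE` and
#' are dropped from the clustering feature matrix downstream (with a log
#' entry), never imputed.
#'
#' @inheritParams species_aspects
#' @param spp Species aspect table from [species_aspects()]; computed if
#'   omitted.
#' @return A tibble: `cell_id`, `taxon`, `module`, `I_c`, `O_c`, `L_c`, the
#'   four aspects, `valid`.
#' @export
cell_aspects <- function(graph, partition, spp = NULL,
                         sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  if (is.null(spp)) spp <- species_aspects(graph, partition, sd_convention)
  retained <- partition$modules$module[partition$modules$retained]
  links <- link_modules(graph, partition)

  counts <- links |>
    group_by(cell_id = .data$cell_id, module = .data$cell_module) |>
    summarise(I_c = sum(.data$species_module == .data$cell_module[1]),
              L_c = n(), .groups = "drop") |>
    mutate(O_c = .data$L_c - .data$I_c) |>
    filter(.data$module %in% retained)

  counts <- counts |>
    group_by(.data$module) |>
    mutate(sd_I = ct_sd(.data$I_c, sd_convention),
           relative_richness = (.data$I_c - mean(.data$I_c)) / .data$sd_I) |>
    ungroup()

  # medians over the characteristic species present in each cell
  med <- links |>
    filter(.data$cell_module == .data$species_module) |>
    inner_join(dplyr::select(spp, "species_id", "z_spp", "c_endem"),
               by = "species_id") |>
    group_by(cell_id = .data$cell_id) |>
    summarise(endemicity = ct_median(.data$c_endem),
              relative_occupancy = ct_median(.data$z_spp),
              n_char = n(), .groups = "drop")

  out <- counts |>
    left_join(med, by = "cell_id") |>
    mutate(valid = !is.na(.data$n_char) & .data$n_char > 0,
           taxon = graph$taxon,
           biota_overlap = .data$O_c / .data$L_c) |>
    dplyr::select("cell_id", "taxon", "module", "I_c", "O_c", "L_c",
                  "relative_richness", "biota_overlap", "endemicity",
                  "relative_occupancy", "valid")
  n_invalid <- sum(!out$valid)
  if (n_invalid > 0) {
    inform(sprintf("cell_aspects: %d cell(s) without characteristic species (valid = FALSE)",
                   n_invalid))
  }
  out
}

#' Pairwise correlations between the four aspects
#'
#' Pearson correlations over all valid cells for the six aspect pairs, with a
#' flag for pairs at or above the collinearity screen threshold (default
#' 0.7 in absolute value). Constant aspects yield `NA` and are flagged as
#' undefined.
#'
#' @param cells Cell aspect table from [cell_aspects()] (or rows of several
#'   taxa bound together).
#' @param threshold Absolute correlation at or above which a pair is flagged.
#' @return A tibble: `aspect_a`, `aspect_b`, `r`, `flagged`, `undefined`.
#' @export
aspect_correlations <- function(cells, threshold = 0.7) {
  aspects <- c("relative_richness", "biota_overlap", "endemicity",
               "relative_occupancy")
  stopifnot_cols(cells, c(aspects, "valid"), "cell aspect table")
  x <- filter(cells, .data$valid)
  if (nrow(x) < 3) {
    ct_abort("need at least 3 valid cells for correlations",
             "coretrans_validation_error")
  }
  pairs <- utils::combn(aspects, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    r <- if (ct_sd(x[[a]]) == 0 || ct_sd(x[[b]]) == 0) NA_real_ else
      cor(x[[a]], x[[b]])
    tibble(aspect_a = a, aspect_b = b, r = r,
           flagged = !is.na(r) && abs(r) >= threshold,
           undefined = is.na(r))
  })
}

#' Enumerate qualitative combinations of the four aspects
#'
#' Crosses a set of qualitative levels (default low / medium / high) over the
#' four biodiversity aspects and returns one row per combination — the
#' combinatorial upper bound on how many distinct kinds of areas the aspects
#' could in principle define (81 for three levels).
#'
#' @param levels Character vector of qualitative levels.
#' @return A tibble with one column per aspect and one row per combination.
#' @export
aspect_level_combinations <- function(levels = c("low", "medium", "high")) {
  as_tibble(expand.grid(
    relative_richness = levels, biota_overlap = levels,
    endemicity = levels, relative_occupancy = levels,
    stringsAsFactors = FALSE
  ))
}
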