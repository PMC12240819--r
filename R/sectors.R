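aspect_cols <- c("relative_richness", "biota_overlap", "endemicity",
                 "relative_occupancy")

# valid rows with the four aspect columns, as a standardized matrix + keys
sector_features <- function(aspects) {
  stopifnot_cols(aspects, c("cell_id", "taxon", aspect_cols, "valid"),
                 "cell aspect table")
  rows <- filter(as_tibble(aspects), .data$valid)
  dropped <- nrow(aspects) - nrow(rows)
  if (dropped > 0) {
    inform(sprintf("sector clustering: dropping %d invalid cell(s)", dropped))
  }
  list(keys = dplyr::select(rows, "cell_id", "taxon"),
       raw = as.matrix(rows[, aspect_cols]),
       std = standardize(rows[, aspect_cols]))
}

#' Taxon-specific sectors: k-means with a GoF-elbow choice of k
#'
#' For each taxon separately: standardize the four aspects over its valid
#' cells, run best-of-restarts weighted k-means for every k in `k_range`,
#' and choose k at the elbow of the GoF curve (piecewise-linear fit with the
#' lowest residual standard error, see [select_k_elbow()]).
#'
#' @param aspects Cell aspect table (possibly several taxa bound together).
#' @param k_range Candidate cluster counts (default 2 to 30).
#' @param restarts k-means restarts per k.
#' @param seed Integer master seed.
#' @param weights Optional per-cell weights, aligned with the valid cells of
#'   each taxon (default uniform).
#' @return A `ct_taxon_sectors`: per-taxon label tibble `cells`
#'   (`cell_id`, `taxon`, `sector`), `chosen_k`, and the `gof_curves`.
#' @export
taxon_specific_sectors <- function(aspects, k_range = 2:30, restarts = 100,
                                   seed = 1L, weights = NULL) {
  if (length(k_range) < 4) {
    ct_abort("k_range must contain >= 4 candidate values for the elbow fit",
             "coretrans_validation_error")
  }
  taxa <- unique(aspects$taxon)
  seeds <- derive_seeds(seed, length(taxa))
  res <- purrr::map2(taxa, seeds, function(tx, sd_tx) {
    feats <- sector_features(filter(aspects, .data$taxon == tx))
    if (nrow(feats$std) < max(k_range)) {
      ct_abort(sprintf("taxon %s has %d valid cells, fewer than max(k_range) = %d",
                       tx, nrow(feats$std), max(k_range)),
               "coretrans_validation_error")
    }
    k_seeds <- derive_seeds(sd_tx, length(k_range))
    fits <- purrr::map2(k_range, k_seeds, function(k, s) {
      weighted_kmeans(feats$std, k, restarts = restarts, seed = s,
                      weights = weights)
    })
    curve <- tibble(k = k_range, gof = purrr::map_dbl(fits, "gof"))
    k_hat <- select_k_elbow(curve)
    labels <- fits[[match(k_hat, k_range)]]$labels
    list(cells = mutate(feats$keys, sector = labels),
         chosen = tibble(taxon = tx, k = k_hat),
         curve = mutate(curve, taxon = tx))
  })
  structure(
    list(cells = purrr::map_dfr(res, "cells"),
         chosen_k = purrr::map_dfr(res, "chosen"),
         gof_curves = purrr::map_dfr(res, "curve")),
    class = "ct_taxon_sectors"
  )
}

#' General sectors: joint k-means selected by mean AMI
#'
#' Clusters all valid cells of all taxa jointly for each candidate k, then
#' compares, per taxon, the joint labels restricted to that taxon with the
#' taxon-specific labels using adjusted mutual information. The k with the
#' highest across-taxa mean AMI wins (ties go to the smallest k). Sectors in
#' the result are renumbered by decreasing centroid relative richness, so
#' sector 1 is the most core-like and the last sector the most
#' transition-like.
#'
#' @param aspects Cell aspect table covering every taxon.
#' @param taxon_partitions A `ct_taxon_sectors` from
#'   [taxon_specific_sectors()].
#' @param k_range Candidate cluster counts for the joint step (default 2 to
#'   14).
#' @param restarts k-means restarts per k.
#' @param seed Integer master seed.
#' @param weight_by_taxon If `TRUE`, weight each cell by the inverse number
#'   of valid cells of its taxon (sensitivity variant); default uniform.
#' @return A `ct_sectors`: `cells` (`cell_id`, `taxon`, `sector`),
#'   `centroids` (per-sector mean raw aspects), `k_general`, `gof`, the full
#'   `ami_table` and its per-k mean.
#' @export
general_sectors <- function(aspects, taxon_partitions, k_range = 2:14,
                            restarts = 100, seed = 1L,
                            weight_by_taxon = FALSE) {
  stopifnot(inherits(taxon_partitions, "ct_taxon_sectors"))
  feats <- sector_features(aspects)
  taxa <- unique(feats$keys$taxon)
  missing_taxa <- setdiff(taxa, taxon_partitions$chosen_k$taxon)
  if (length(missing_taxa) > 0) {
    ct_abort(sprintf("no taxon-specific partition for: %s",
                     paste(missing_taxa, collapse = ", ")),
             "coretrans_validation_error")
  }
  weights <- if (weight_by_taxon) {
    cnt <- table(feats$keys$taxon)
    as.numeric(1 / cnt[feats$keys$taxon])
  } else NULL

  ref <- feats$keys |>
    left_join(rename(taxon_partitions$cells, ref_sector = "sector"),
              by = c("cell_id", "taxon"))
  if (anyNA(ref$ref_sector)) {
    ct_abort("taxon partitions do not cover every valid cell",
             "coretrans_validation_error")
  }

  k_seeds <- derive_seeds(seed, length(k_range))
  fits <- purrr::map2(k_range, k_seeds, function(k, s) {
    weighted_kmeans(feats$std, k, restarts = restarts, seed = s,
                    weights = weights)
  })
  ami_table <- purrr::map2_dfr(k_range, fits, function(k, fit) {
    purrr::map_dfr(taxa, function(tx) {
      sel <- feats$keys$taxon == tx
      tibble(k = k, taxon = tx,
             ami = ami(fit$labels[sel], ref$ref_sector[sel]))
    })
  })
  mean_ami <- ami_table |>
    group_by(.data$k) |>
    summarise(mean_ami = mean(.data$ami), .groups = "drop") |>
    arrange(.data$k)
  best <- mean_ami$k[which.max(mean_ami$mean_ami)]  # first max = smallest k
  fit <- fits[[match(best, k_range)]]

  # canonical core-to-transition order: 1 = highest centroid relative richness
  raw_cent <- rowsum(feats$raw, fit$labels) / as.vector(table(fit$labels))
  ord <- order(raw_cent[, "relative_richness"], decreasing = TRUE)
  relabel <- match(seq_len(nrow(raw_cent)), ord)
  cells <- mutate(feats$keys, sector = relabel[fit$labels])
  centroids <- as_tibble(raw_cent[ord, , drop = FALSE]) |>
    mutate(sector = seq_along(ord),
           n_cells = as.vector(table(cells$sector))) |>
    dplyr::select("sector", "n_cells", dplyr::all_of(aspect_cols))

  structure(
    list(cells = cells, centroids = centroids, k_general = best,
         gof = fit$gof, ami_table = ami_table, mean_ami = mean_ami,
         taxon_k = taxon_partitions$chosen_k,
         weight_by_taxon = weight_by_taxon),
    class = "ct_sectors"
  )
}

#' @export
print.ct_sectors <- function(x, ...) {
  cat(sprintf(
    "<ct_sectors> k = %d over %d cells (%d taxa), GoF %.3f, mean AMI %.3f\n",
    x$k_general, nrow(x$cells), n_distinct(x$cells$taxon), x$gof,
    max(x$mean_ami$mean_ami)))
  invisible(x)
}
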