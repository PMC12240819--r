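#' Tidy a bioregion partition
#'
#' @param x A `ct_partition`.
#' @param ... Unused.
#' @return One row per node: `node`, `type`, `module`, `retained`.
#' @export
tidy.ct_partition <- function(x, ...) {
  x$nodes |>
    left_join(dplyr::select(x$modules, "module", "retained"), by = "module")
}

#' @rdname tidy.ct_partition
#' @export
glance.ct_partition <- function(x, ...) {
  tibble(
    backend = x$backend, n_trials = x$n_trials, codelength = x$codelength,
    n_modules = nrow(x$modules), n_retained = sum(x$modules$retained),
    n_cells = sum(x$nodes$type == "cell"),
    n_species = sum(x$nodes$type == "species")
  )
}

#' Tidy a sector assignment
#'
#' @param x A `ct_sectors`.
#' @param ... Unused.
#' @return One row per cell: `cell_id`, `taxon`, `sector`.
#' @export
tidy.ct_sectors <- function(x, ...) x$cells

#' @rdname tidy.ct_sectors
#' @export
glance.ct_sectors <- function(x, ...) {
  tibble(
    k_general = x$k_general, gof = x$gof,
    mean_ami = max(x$mean_ami$mean_ami),
    n_cells = nrow(x$cells), n_taxa = n_distinct(x$cells$taxon),
    weight_by_taxon = x$weight_by_taxon
  )
}

#' Tidy a multinomial sector-environment fit
#'
#' @param x A `ct_multinom`.
#' @param ... Unused.
#' @return One row per (class, term) coefficient.
#' @export
tidy.ct_multinom <- function(x, ...) {
  cf <- x$coefficients
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1, dimnames = list("2", names(cf)))
  as_tibble(cf, rownames = "class") |>
    tidyr::pivot_longer(-"class", names_to = "term", values_to = "estimate")
}

#' @rdname tidy.ct_multinom
#' @export
glance.ct_multinom <- function(x, ...) {
  tibble(logLik = x$logLik, logLik_null = x$logLik_null, aicc = x$aicc,
         aicc_null = x$aicc_null, pseudo_r2 = x$pseudo_r2,
         delta_aicc = x$aicc_null - x$aicc,
         n = x$n, K = x$K, converged = x$converged)
}
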