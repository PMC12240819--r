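#' Build the species-by-cell bipartite network
#'
#' Species and grid cells are the two node types; one link per presence.
#'
#' @param occurrences Occurrence tibble (`taxon`, `species_id`, `cell_id`)
#'   for a single taxon, as from [read_occurrences()] or
#'   [generate_landscape()].
#' @return A `ct_bigraph` with the link table, node vectors and degrees.
#' @export
build_bipartite <- function(occurrences) {
  stopifnot_cols(occurrences, c("species_id", "cell_id"), "occurrence table")
  if (nrow(occurrences) == 0) {
    ct_abort("cannot build a bipartite graph from an empty dataset",
             "coretrans_empty_input")
  }
  taxon <- if ("taxon" %in% names(occurrences)) unique(occurrences$taxon) else "unknown"
  if (length(taxon) > 1) {
    ct_abort("build_bipartite expects records of a single taxon; split by taxon first",
             "coretrans_validation_error")
  }
  links <- distinct(as_tibble(occurrences), .data$species_id, .data$cell_id)
  cells <- sort(unique(links$cell_id))
  species <- sort(unique(links$species_id))
  structure(
    list(
      taxon = taxon,
      links = links,
      cells = cells,
      species = species,
      cell_degree = table(factor(links$cell_id, levels = cells)),
      species_degree = table(factor(links$species_id, levels = species))
    ),
    class = "ct_bigraph"
  )
}

#' @export
print.ct_bigraph <- function(x, ...) {
  cat(sprintf("<ct_bigraph taxon=%s> %d cells, %d species, %d links\n",
              x$taxon, length(x$cells), length(x$species), nrow(x$links)))
  invisible(x)
}

# igraph object with cells first, then species; vertex name = node id
as_igraph <- function(graph) {
  nodes <- c(graph$cells, graph$species)
  idx <- setNames(seq_along(nodes), nodes)
  edges <- cbind(idx[graph$links$cell_id], idx[graph$links$species_id])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$name <- nodes
  igraph::V(g)$type <- c(rep(FALSE, length(graph$cells)),
                         rep(TRUE, length(graph$species)))
  g
}

#' Two-level map equation of a partition
#'
#' Evaluates the two-level map-equation codelength (bits) of a hard node
#' partition on an undirected, unweighted network, using node visit rates
#' proportional to degree and module exit rates proportional to boundary
#' links. This is the information-theoretic objective minimised by
#' flow-compression community detection; the package uses it as the uniform
#' selection criterion across partition backends (lower is better).
#'
#' @param edges Two-column integer matrix of node indices (one row per
#'   undirected link).
#' @param membership Integer module id per node (length = number of nodes).
#' @return Codelength in bits.
#' @export
map_equation <- function(edges, membership) {
  n <- length(membership)
  m <- nrow(edges)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  p <- deg / (2 * m)
  mods <- sort(unique(membership))
  mod_idx <- match(membership, mods)
  inter <- mod_idx[edges[, 1]] != mod_idx[edges[, 2]]
  w_out <- tabulate(c(mod_idx[edges[inter, 1]], mod_idx[edges[inter, 2]]),
                    nbins = length(mods))
  q <- w_out / (2 * m)
  Q <- sum(q)
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  index_term <- if (Q > 0) -Q * sum(plogp(q / Q)) else 0
  module_term <- 0
  for (i in seq_along(mods)) {
    pa <- p[mod_idx == i]
    pm <- q[i] + sum(pa)
    if (pm > 0) {
      module_term <- module_term -
        pm * (sum(plogp(pa / pm)) + plogp(q[i] / pm))
    }
  }
  index_term + module_term
}
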