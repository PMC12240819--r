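#' Count cross-sector neighbour relations within regions
#'
#' For each region (bioregion) and each ordered sector pair A -> B: `n` is
#' the number of neighbour instances of A-cells whose neighbour lies in the
#' same region but a different sector, and `x` is how many of those
#' neighbours belong to B. Each adjacent ordered cell pair counts once.
#'
#' @param grid Grid table with `cell_id`, `row`, `col`.
#' @param assignment A `ct_sectors` or a data frame with `cell_id`, `sector`.
#' @param cell_modules Data frame `cell_id`, `module` giving each cell's
#'   region (e.g. from a `ct_partition`'s nodes).
#' @param scheme `"queen"` (8 neighbours, default) or `"rook"` (4).
#' @return A tibble: `module`, `sector_a`, `sector_b`, `x`, `n` (with `n`
#'   the A-row total over all B).
#' @export
adjacency_counts <- function(grid, assignment, cell_modules,
                             scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  cells <- if (inherits(assignment, "ct_sectors")) assignment$cells else as_tibble(assignment)
  stopifnot_cols(cells, c("cell_id", "sector"), "sector assignment")
  stopifnot_cols(cell_modules, c("cell_id", "module"), "cell_modules")
  if (!all(cells$cell_id %in% grid$cell_id)) {
    ct_abort("assigned cell(s) missing from the grid", "coretrans_validation_error")
  }
  info <- cells |>
    dplyr::select("cell_id", "sector") |>
    inner_join(dplyr::select(cell_modules, "cell_id", "module"), by = "cell_id") |>
    inner_join(dplyr::select(grid, "cell_id", "row", "col"), by = "cell_id")

  pairs <- neighbor_pairs(info, scheme)
  directed <- pairs |>
    filter(.data$module_a == .data$module_b, .data$sector_a != .data$sector_b) |>
    count(module = .data$module_a, .data$sector_a, .data$sector_b, name = "x")
  directed |>
    group_by(.data$module, .data$sector_a) |>
    mutate(n = sum(.data$x)) |>
    ungroup()
}

# all ordered neighbour cell pairs with sector/module of both ends
neighbor_pairs <- function(info, scheme) {
  offsets <- if (scheme == "queen") {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  purrr::map_dfr(seq_len(nrow(offsets)), function(i) {
    shifted <- mutate(info, row = .data$row + offsets$dr[i],
                      col = .data$col + offsets$dc[i])
    inner_join(
      rename(info, sector_a = "sector", module_a = "module", cell_a = "cell_id"),
      rename(shifted, sector_b = "sector", module_b = "module", cell_b = "cell_id"),
      by = c("row", "col")
    )
  })
}

#' One-sided binomial tests of sector adjacency
#'
#' Tests, per region and unordered sector pair, whether the observed
#' probability that a cross-sector neighbour of sector A belongs to sector B
#' exceeds the chance expectation `p0` (1 in 6 under seven sectors), in both
#' directions. A pair is significant when either direction yields
#' `p < alpha`. Directions require more than `min_n` neighbouring instances;
#' pairs with no testable direction are excluded with a reason.
#'
#' The default decision rule is the exact binomial tail; `method = "prop"`
#' gives the continuity-corrected normal approximation (the behaviour of
#' `prop.test`).
#'
#' @param counts Output of [adjacency_counts()].
#' @param p0 Null adjacency probability.
#' @param alpha Significance level.
#' @param min_n Minimum neighbour instances (strictly greater than) for a
#'   direction to be tested.
#' @param method `"exact"` or `"prop"`.
#' @return A list with `tests` (per region and unordered pair: `p_ab`,
#'   `p_ba`, `tested`, `significant`, `reason`) and `pair_frequency` (per
#'   unordered sector pair across regions: tested and significant counts and
#'   the relative frequency of significance).
#' @export
neighbor_tests <- function(counts, p0 = 1 / 6, alpha = 0.05, min_n = 30,
                           method = c("exact", "prop")) {
  method <- match.arg(method)
  counts <- as_tibble(counts)
  stopifnot_cols(counts, c("module", "sector_a", "sector_b", "x", "n"),
                 "adjacency counts")
  und <- counts |>
    mutate(lo = pmin(.data$sector_a, .data$sector_b),
           hi = pmax(.data$sector_a, .data$sector_b),
           dir = if_else(.data$sector_a == .data$lo, "ab", "ba")) |>
    dplyr::select("module", "lo", "hi", "dir", "x", "n") |>
    tidyr::pivot_wider(names_from = "dir", values_from = c("x", "n"))
  for (col in c("x_ab", "n_ab", "x_ba", "n_ba")) {
    if (!col %in% names(und)) und[[col]] <- NA_integer_
    und[[col]][is.na(und[[col]])] <- 0L
  }
  tests <- und |>
    mutate(
      test_ab = .data$n_ab > min_n,
      test_ba = .data$n_ba > min_n,
      p_ab = if_else(.data$test_ab,
                     binom_upper_p(.data$x_ab, .data$n_ab, p0, method), NA_real_),
      p_ba = if_else(.data$test_ba,
                     binom_upper_p(.data$x_ba, .data$n_ba, p0, method), NA_real_),
      tested = .data$test_ab | .data$test_ba,
      significant = (.data$tested &
        ((!is.na(.data$p_ab) & .data$p_ab < alpha) |
         (!is.na(.data$p_ba) & .data$p_ba < alpha))),
      reason = if_else(.data$tested, NA_character_, "insufficient neighbours")
    ) |>
    dplyr::select("module", sector_a = "lo", sector_b = "hi",
                  "x_ab", "n_ab", "x_ba", "n_ba",
                  "p_ab", "p_ba", "tested", "significant", "reason")
  pair_frequency <- tests |>
    filter(.data$tested) |>
    group_by(.data$sector_a, .data$sector_b) |>
    summarise(n_tested = n(), n_significant = sum(.data$significant),
              frequency = mean(.data$significant), .groups = "drop")
  list(tests = tests, pair_frequency = pair_frequency,
       p0 = p0, alpha = alpha, min_n = min_n, method = method)
}

# Upper-tail p-value for x successes out of n at null probability p0.
binom_upper_p <- function(x, n, p0, method = c("exact", "prop")) {
  method <- match.arg(method)
  if (method == "exact") {
    return(pbinom(x - 1, n, p0, lower.tail = FALSE))
  }
  # one-sided chi-square score test with Yates continuity correction,
  # algebraically identical to prop.test(alternative = "greater")
  phat <- x / n
  diff <- phat - p0
  z <- (diff - sign(diff) * pmin(0.5 / n, abs(diff))) /
    sqrt(p0 * (1 - p0) / n)
  stats::pnorm(z, lower.tail = FALSE)
}
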