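strip_setup <- function(sectors, rows = 1) {
  grid <- lattice_grid(rows, length(sectors) / rows)
  assignment <- tibble::tibble(cell_id = grid$cell_id, taxon = "tx",
                               sector = sectors)
  modules <- tibble::tibble(cell_id = grid$cell_id, module = 1L)
  list(grid = grid, assignment = assignment, modules = modules)
}

test_that("a single boundary contact is counted once per direction", {
  s <- strip_setup(c(1L, 1L, 2L, 2L))
  counts <- adjacency_counts(s$grid, s$assignment, s$modules, scheme = "rook")
  ab <- counts[counts$sector_a == 1, ]
  expect_equal(ab$x, 1L)
  expect_equal(ab$n, 1L)
  ba <- counts[counts$sector_a == 2, ]
  expect_equal(ba$x, 1L)
})

test_that("checkerboard contacts are symmetric under queen adjacency", {
  s <- strip_setup(c(1L, 2L, 2L, 1L), rows = 2)  # 2x2 checkerboard
  q <- adjacency_counts(s$grid, s$assignment, s$modules, scheme = "queen")
  x_ab <- sum(q$x[q$sector_a == 1 & q$sector_b == 2])
  x_ba <- sum(q$x[q$sector_a == 2 & q$sector_b == 1])
  expect_equal(x_ab, x_ba)
  r <- adjacency_counts(s$grid, s$assignment, s$modules, scheme = "rook")
  expect_true(sum(q$n) >= sum(r$n))
})

test_that("neighbour counts match a brute-force enumeration oracle", {
  grid <- lattice_grid(6, 6)
  assignment <- withr::with_seed(4, tibble::tibble(
    cell_id = grid$cell_id, taxon = "tx",
    sector = sample(1:3, 36, replace = TRUE)))
  modules <- tibble::tibble(cell_id = grid$cell_id,
                            module = rep(1:2, each = 18))
  for (scheme in c("queen", "rook")) {
    counts <- adjacency_counts(grid, assignment, modules, scheme = scheme)
    # oracle: loop over all cell pairs
    info <- merge(merge(as.data.frame(assignment), as.data.frame(modules)),
                  as.data.frame(grid))
    tally <- list()
    for (i in seq_len(nrow(info))) {
      for (j in seq_len(nrow(info))) {
        if (i == j) next
        dr <- abs(info$row[i] - info$row[j])
        dc <- abs(info$col[i] - info$col[j])
        adjacent <- if (scheme == "queen") max(dr, dc) == 1 else dr + dc == 1
        if (!adjacent) next
        if (info$module[i] != info$module[j]) next
        if (info$sector[i] == info$sector[j]) next
        key <- paste(info$module[i], info$sector[i], info$sector[j])
        tally[[key]] <- (tally[[key]] %||% 0) + 1
      }
    }
    for (r in seq_len(nrow(counts))) {
      key <- paste(counts$module[r], counts$sector_a[r], counts$sector_b[r])
      expect_equal(counts$x[r], tally[[key]],
                   info = paste(scheme, key))
    }
    expect_equal(nrow(counts), length(tally))
  }
})

test_that("exact decisions match the binomial tail oracle exhaustively", {
  p0 <- 1 / 6
  alpha <- 0.05
  for (n in c(31, 40, 57, 100, 161, 200)) {
    x <- 0:n
    p_pkg <- coretrans:::binom_upper_p(x, n, p0, "exact")
    p_ora <- sapply(x, oracle_binom_tail, n = n, p0 = p0)
    expect_equal(p_pkg, p_ora, tolerance = 1e-12)
    expect_identical(p_pkg < alpha, p_ora < alpha)
  }
})

test_that("the 'prop' method reproduces prop.test p-values", {
  cases <- withr::with_seed(12, data.frame(n = sample(2:200, 200, TRUE)))
  cases$x <- vapply(cases$n, function(n) sample(0:n, 1), integer(1))
  p_pkg <- coretrans:::binom_upper_p(cases$x, cases$n, 1 / 6, "prop")
  p_ref <- mapply(function(x, n) {
    suppressWarnings(prop.test(x, n, p = 1 / 6, alternative = "greater",
                               correct = TRUE)$p.value)
  }, cases$x, cases$n)
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)
})

test_that("neighbour tests apply the threshold, null and both directions", {
  counts <- tibble::tibble(
    module = 1L,
    sector_a = c(1L, 2L, 1L, 3L, 2L, 3L),
    sector_b = c(2L, 1L, 3L, 1L, 3L, 2L),
    x = c(6L, 24L, 10L, 2L, 5L, 4L),
    n = c(36L, 36L, 30L, 31L, 31L, 31L)
  )
  res <- neighbor_tests(counts, min_n = 30)
  t12 <- res$tests[res$tests$sector_a == 1 & res$tests$sector_b == 2, ]
  # x = 6 of 36 is exactly the null proportion -> not significant;
  # the reverse direction x = 24 of 36 is overwhelming
  expect_true(t12$significant)
  expect_gt(t12$p_ab, 0.5)
  expect_lt(t12$p_ba, 1e-10)

  # pair (1,3): direction A->B has n = 30, not > 30; B->A has n = 31
  t13 <- res$tests[res$tests$sector_a == 1 & res$tests$sector_b == 3, ]
  expect_true(is.na(t13$p_ab))
  expect_false(is.na(t13$p_ba))

  # a pair untested in both directions is excluded with a reason
  few <- neighbor_tests(dplyr::mutate(counts, n = 30L), min_n = 30)
  expect_true(all(!few$tests$tested))
  expect_true(all(few$tests$reason == "insufficient neighbours"))
  expect_equal(nrow(few$pair_frequency), 0)
})

test_that("null-shuffled sector labels stay within the nominal level", {
  # seven sectors, so the fixed null of 1 in 6 is the true chance level
  grid <- lattice_grid(20, 20)
  modules <- tibble::tibble(cell_id = grid$cell_id, module = 1L)
  n_shuffle <- 300
  rates <- withr::with_seed(31, {
    tested <- 0; significant <- 0
    for (i in seq_len(n_shuffle)) {
      assignment <- tibble::tibble(cell_id = grid$cell_id, taxon = "tx",
                                   sector = sample(rep(1:7, length.out = 400)))
      counts <- adjacency_counts(grid, assignment, modules)
      res <- neighbor_tests(counts, min_n = 30)
      tested <- tested + sum(!is.na(res$tests$p_ab)) +
        sum(!is.na(res$tests$p_ba))
      significant <- significant +
        sum(res$tests$p_ab < 0.05, na.rm = TRUE) +
        sum(res$tests$p_ba < 0.05, na.rm = TRUE)
    }
    c(tested = tested, significant = significant)
  })
  rate <- rates["significant"] / rates["tested"]
  # conservative exact test: per-direction rejection rate at or below alpha
  # (plus 3 binomial standard errors of Monte-Carlo noise)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / rates["tested"]))
})
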