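#' Region eligibility for multinomial environmental models
#'
#' A region is eligible when, after keeping only sectors with more than
#' `min_cells` grid cells, at least two sectors remain and the kept sectors
#' cover at least `min_coverage` of the region's cells.
#'
#' @param assignment A `ct_sectors` or data frame with `cell_id`, `sector`.
#' @param cell_modules Data frame `cell_id`, `module`.
#' @param min_cells Minimum cells per retained sector (strictly greater
#'   than; default 15).
#' @param min_coverage Minimum fraction of the region covered by retained
#'   sectors (default 0.9).
#' @return A tibble: `module`, `n_cells`, `n_sectors`, `retained_sectors`
#'   (list-column), `coverage`, `eligible`.
#' @export
eligible_regions <- function(assignment, cell_modules, min_cells = 15,
                             min_coverage = 0.9) {
  cells <- if (inherits(assignment, "ct_sectors")) assignment$cells else as_tibble(assignment)
  stopifnot_cols(cells, c("cell_id", "sector"), "sector assignment")
  tab <- cells |>
    inner_join(dplyr::select(cell_modules, "cell_id", "module"), by = "cell_id") |>
    count(.data$module, .data$sector, name = "size")
  tab |>
    group_by(.data$module) |>
    summarise(
      n_cells = sum(.data$size),
      n_sectors = n(),
      retained_sectors = list(.data$sector[.data$size > min_cells]),
      coverage = sum(.data$size[.data$size > min_cells]) / sum(.data$size),
      .groups = "drop"
    ) |>
    mutate(eligible = purrr::map_int(.data$retained_sectors, length) >= 2 &
             .data$coverage >= min_coverage)
}

#' Fit a multinomial logit of sector on environmental covariates
#'
#' Maximum-likelihood softmax regression (via [nnet::multinom()]) of the
#' sector label on standardized covariates, with the largest sector as the
#' reference class, plus the intercept-only null fit on the same rows.
#' Reports the small-sample corrected AIC (AICc with
#' `k = (K - 1) * (p + 1)` parameters and `n` cells) and McFadden's
#' pseudo-R2 `1 - logLik(model) / logLik(null)`.
#'
#' @param data Data frame with a `sector` column and one column per
#'   covariate; no missing values.
#' @param covariates Character vector of covariate column names.
#' @param max_iter Optimizer iteration cap.
#' @return A `ct_multinom` list: `coefficients`, `logLik`, `logLik_null`,
#'   `aicc`, `aicc_null`, `pseudo_r2`, `converged`, `n`, `K`, `p`.
#' @export
fit_sector_multinomial <- function(data, covariates, max_iter = 500) {
  stopifnot_cols(data, c("sector", covariates), "model data")
  data <- as_tibble(data)
  if (anyNA(data[, c("sector", covariates)])) {
    ct_abort("missing values in model data", "coretrans_validation_error")
  }
  y <- factor(data$sector)
  if (nlevels(y) < 2) {
    ct_abort("need >= 2 sector classes to fit a multinomial model",
             "coretrans_validation_error")
  }
  y <- stats::relevel(y, ref = names(which.max(table(y))))
  X <- as.matrix(data[, covariates, drop = FALSE])
  # standardize internally; constant columns carry no information -> zeroed
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  X <- sweep(X, 2, ctr)
  X[, scl > 0] <- sweep(X[, scl > 0, drop = FALSE], 2, scl[scl > 0], "/")
  df <- data.frame(.sector = y, X)

  fit <- nnet::multinom(.sector ~ ., data = df, trace = FALSE,
                        maxit = max_iter, reltol = 1e-10)
  null_fit <- nnet::multinom(.sector ~ 1, data = df, trace = FALSE,
                             maxit = max_iter, reltol = 1e-10)
  n <- nrow(df); K <- nlevels(y); p <- length(covariates)
  ll <- as.numeric(logLik(fit)); ll0 <- as.numeric(logLik(null_fit))
  structure(
    list(
      coefficients = coef(fit),
      logLik = ll, logLik_null = ll0,
      aicc = aicc_value(ll, (K - 1) * (p + 1), n),
      aicc_null = aicc_value(ll0, K - 1, n),
      pseudo_r2 = max(0, 1 - ll / ll0),
      converged = fit$convergence == 0,
      n = n, K = K, p = p
    ),
    class = "ct_multinom"
  )
}

aicc_value <- function(ll, k, n) {
  aic <- -2 * ll + 2 * k
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare a multinomial fit to its null by AICc
#'
#' The environmental association is deemed significant when the null's AICc
#' exceeds the model's by strictly more than `threshold` (default 10).
#'
#' @param fit,null_fit `ct_multinom` objects on identical rows (`null_fit`
#'   may be omitted: the null stored in `fit` is used).
#' @param threshold AICc difference required.
#' @return A list: `delta_aicc`, `significant`.
#' @export
compare_to_null <- function(fit, null_fit = NULL, threshold = 10) {
  stopifnot(inherits(fit, "ct_multinom"))
  aicc_null <- if (is.null(null_fit)) fit$aicc_null else {
    if (null_fit$n != fit$n) {
      ct_abort("model and null were fitted on different rows",
               "coretrans_validation_error")
    }
    null_fit$aicc
  }
  delta <- aicc_null - fit$aicc
  list(delta_aicc = delta, significant = delta > threshold)
}

#' Environmental models for every eligible region
#'
#' Runs [fit_sector_multinomial()] + [compare_to_null()] for each eligible
#' region of a sector assignment, using the cells of that region and its
#' retained sectors only.
#'
#' @param assignment A `ct_sectors`.
#' @param env Environmental table (`cell_id` + covariate columns).
#' @param cell_modules Data frame `cell_id`, `module`.
#' @param covariates Covariate column names (default: all non-`cell_id`
#'   columns of `env`).
#' @param threshold AICc difference for significance.
#' @inheritParams eligible_regions
#' @return A tibble with one row per eligible region: `module`, `taxon`,
#'   `n`, `K`, `logLik`, `aicc`, `delta_aicc`, `pseudo_r2`, `converged`,
#'   `significant`.
#' @export
sector_env_models <- function(assignment, env, cell_modules,
                              covariates = NULL, threshold = 10,
                              min_cells = 15, min_coverage = 0.9) {
  stopifnot(inherits(assignment, "ct_sectors"))
  covariates <- covariates %||% setdiff(names(env), "cell_id")
  elig <- eligible_regions(assignment, cell_modules, min_cells, min_coverage)
  regions <- filter(elig, .data$eligible)
  if (nrow(regions) == 0) {
    inform("sector_env_models: no eligible region")
    return(tibble())
  }
  cells <- assignment$cells |>
    inner_join(dplyr::select(cell_modules, "cell_id", "module"), by = "cell_id") |>
    inner_join(env, by = "cell_id")
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    mod <- regions$module[i]
    keep <- regions$retained_sectors[[i]]
    dat <- filter(cells, .data$module == mod, .data$sector %in% keep)
    fit <- fit_sector_multinomial(dat, covariates)
    cmp <- compare_to_null(fit, threshold = threshold)
    if (!fit$converged) {
      inform(sprintf("sector_env_models: region %s did not converge; excluded from summaries", mod))
    }
    tibble(module = mod, taxon = dat$taxon[1] %||% NA_character_,
           n = fit$n, K = fit$K, logLik = fit$logLik, aicc = fit$aicc,
           delta_aicc = cmp$delta_aicc, pseudo_r2 = fit$pseudo_r2,
           converged = fit$converged, significant = cmp$significant)
  })
}
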