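#' Standardize an aspect feature matrix
#'
#' Column-wise z-scoring (sample sd) with the scaling parameters kept as
#' attributes for the inverse transform. Applied before any k-means run so
#' the four aspects contribute on comparable scales.
#'
#' @param features Numeric matrix or data frame of features (no missing
#'   values, at least 2 rows).
#' @return A numeric matrix with attributes `center` and `scale`.
#' @export
standardize <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 2) ct_abort("need >= 2 rows to standardize", "coretrans_validation_error")
  if (anyNA(x)) ct_abort("missing values in feature matrix", "coretrans_validation_error")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    ct_abort(sprintf("zero-variance column(s): %s",
                     paste(colnames(x)[scl == 0], collapse = ", ")),
             "coretrans_validation_error")
  }
  out <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Weighted k-means with seeded restarts
#'
#' Lloyd's algorithm with per-observation weights: centroids are weighted
#' means of their members, and the goodness of fit (GoF) is the weighted
#' between-cluster sum of squares divided by the weighted total sum of
#' squares. The best of `restarts` independently seeded runs (highest GoF)
#' is returned. Uniform weights reduce exactly to ordinary k-means.
#'
#' @param x Numeric matrix (rows = observations).
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param restarts Number of random restarts.
#' @param seed Integer master seed; restart seeds are derived from it.
#' @param weights Non-negative per-row weights (default uniform).
#' @param max_iter Iteration cap per run.
#' @return A list: `labels` (integer vector), `centers`, `gof`, `iter`.
#' @export
weighted_kmeans <- function(x, k, restarts = 100, seed = 1L, weights = NULL,
                            max_iter = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is_count(k) || k < 1) ct_abort("k must be a positive integer", "coretrans_validation_error")
  if (k > n) ct_abort(sprintf("k = %d exceeds the %d available rows", k, n),
                      "coretrans_validation_error")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) {
    ct_abort("weights must be non-negative, one per row", "coretrans_validation_error")
  }
  wtot <- sum(weights)
  ctr_w <- colSums(x * weights) / wtot
  tss <- sum(weights * rowSums(sweep(x, 2, ctr_w)^2))
  seeds <- derive_seeds(seed, restarts)

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- withr::with_seed(seeds[r], lloyd_once(x, k, weights, max_iter))
    gof <- if (tss > 0) 1 - fit$wss / tss else 0
    if (is.null(best) || gof > best$gof + 1e-15) {
      best <- list(labels = fit$labels, centers = fit$centers, gof = gof,
                   iter = fit$iter)
    }
  }
  if (k == 1) best$gof <- 0  # no between-cluster variance by definition
  best
}

lloyd_once <- function(x, k, weights, max_iter) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  labels <- integer(n)
  xsq <- rowSums(x^2)
  for (it in seq_len(max_iter)) {
    d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * x %*% t(centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters with the worst-fit point
    for (j in setdiff(seq_len(k), unique(new_labels))) {
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      new_labels[far] <- j
      d2[far, ] <- Inf; d2[far, j] <- 0
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    wsum <- rowsum(x * weights, labels)
    wcnt <- rowsum(weights, labels)
    centers <- wsum / as.vector(wcnt)
  }
  wss <- sum(weights * rowSums((x - centers[labels, , drop = FALSE])^2))
  list(labels = labels, centers = centers, wss = wss, iter = it)
}

#' Choose k at the elbow of a GoF curve
#'
#' Fits, at every interior candidate breakpoint, a continuous two-segment
#' piecewise linear model of GoF against k (brute-force search) and returns
#' the breakpoint minimising the residual standard error; ties go to the
#' smallest k.
#'
#' @param curve Data frame with columns `k` and `gof` (>= 4 rows).
#' @return The selected k (integer).
#' @export
select_k_elbow <- function(curve) {
  stopifnot_cols(curve, c("k", "gof"), "GoF curve")
  curve <- arrange(as_tibble(curve), .data$k)
  n <- nrow(curve)
  if (n < 4) ct_abort("elbow selection needs >= 4 (k, GoF) points",
                      "coretrans_validation_error")
  ks <- curve$k; y <- curve$gof
  cand <- ks[2:(n - 1)]
  rse <- purrr::map_dbl(cand, function(b) {
    X <- cbind(1, ks, pmax(ks - b, 0))
    fit <- stats::lm.fit(X, y)
    sqrt(sum(fit$residuals^2) / (n - 3))
  })
  # smallest k among (near-)ties of the minimum
  tol <- 1e-10 * (1 + min(rse))
  cand[which(rse <= min(rse) + tol)[1]]
}
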