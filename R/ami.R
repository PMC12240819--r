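#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance under the permutation
#' (hypergeometric) model and normalised by the arithmetic mean of the two
#' label entropies. Equals 1 iff the labelings are identical up to
#' relabelling; hovers around 0 for independent labelings and can be
#' negative.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return A single value in `(-Inf, 1]`.
#' @export
ami <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    ct_abort("labelings must have equal length", "coretrans_validation_error")
  }
  n <- length(labels_a)
  if (n < 2) ct_abort("labelings must have length >= 2", "coretrans_validation_error")
  tab <- table(labels_a, labels_b)
  a <- rowSums(tab)
  b <- colSums(tab)

  h_a <- entropy_nat(a / n)
  h_b <- entropy_nat(b / n)
  if (h_a == 0 && h_b == 0) return(1)  # both trivial one-cluster labelings

  nij <- as.vector(tab)
  ai <- rep(a, times = length(b))
  bj <- rep(b, each = length(a))
  pos <- nij > 0
  mi <- sum((nij[pos] / n) * log(n * nij[pos] / (ai[pos] * bj[pos])))

  emi <- expected_mi(a, b, n)
  denom <- (h_a + h_b) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (mi - emi) / denom
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Exact expected mutual information under random permutations of one labeling
# against the other with fixed marginals (hypergeometric model).
expected_mi <- function(a, b, n) {
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      k <- lo:hi
      w <- dhyper(k, a[i], n - a[i], b[j])
      emi <- emi + sum(w * (k / n) * log(n * k / (a[i] * b[j])))
    }
  }
  emi
}
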