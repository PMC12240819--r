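# Independent brute-force oracles (base-R loops over raw link lists),
# deliberately written without the package's vectorised code paths.

# per-node recomputation of the four cell aspects and two species aspects
oracle_aspects <- function(links, modules, retained) {
  species <- unique(links$species_id)
  cells <- unique(links$cell_id)
  sp_mod <- modules[species]
  cl_mod <- modules[cells]

  I_s <- L_s <- setNames(numeric(length(species)), species)
  for (s in species) {
    rows <- links[links$species_id == s, ]
    L_s[s] <- nrow(rows)
    I_s[s] <- sum(modules[rows$cell_id] == sp_mod[s])
  }
  z_spp <- setNames(rep(NA_real_, length(species)), species)
  for (m in retained) {
    in_m <- names(sp_mod)[sp_mod == m]
    z_spp[in_m] <- (I_s[in_m] - mean(I_s[in_m])) / stats::sd(I_s[in_m])
  }
  c_endem <- I_s / L_s

  out <- list()
  for (cl in cells) {
    m <- cl_mod[cl]
    if (!(m %in% retained)) next
    rows <- links[links$cell_id == cl, ]
    L_c <- nrow(rows)
    I_c <- sum(modules[rows$species_id] == m)
    module_cells <- names(cl_mod)[cl_mod == m]
    Ic_all <- sapply(module_cells, function(cc) {
      rr <- links[links$cell_id == cc, ]
      sum(modules[rr$species_id] == m)
    })
    char_sp <- rows$species_id[modules[rows$species_id] == m]
    out[[cl]] <- data.frame(
      cell_id = cl,
      I_c = I_c, O_c = L_c - I_c, L_c = L_c,
      relative_richness = (I_c - mean(Ic_all)) / stats::sd(Ic_all),
      biota_overlap = (L_c - I_c) / L_c,
      endemicity = if (length(char_sp)) stats::median(c_endem[char_sp]) else NA_real_,
      relative_occupancy = if (length(char_sp)) stats::median(z_spp[char_sp]) else NA_real_
    )
  }
  do.call(rbind, out)
}

# multi-site Sorensen components via explicit pairwise set operations
oracle_beta <- function(m) {
  m <- m > 0
  sets <- apply(m, 1, function(r) which(r), simplify = FALSE)
  n <- length(sets)
  sum_min <- sum_max <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      bij <- length(setdiff(sets[[i]], sets[[j]]))
      bji <- length(setdiff(sets[[j]], sets[[i]]))
      sum_min <- sum_min + min(bij, bji)
      sum_max <- sum_max + max(bij, bji)
    }
  }
  core <- sum(lengths(sets)) - length(unique(unlist(sets)))
  sim <- if (core + sum_min > 0) sum_min / (core + sum_min) else 0
  sor <- if (2 * core + sum_min + sum_max > 0) {
    (sum_min + sum_max) / (2 * core + sum_min + sum_max)
  } else 0
  list(beta_sim = sim, beta_sor = sor, beta_sne = sor - sim)
}

# exact one-sided binomial tail by direct summation of choose() terms
oracle_binom_tail <- function(x, n, p0) {
  if (x <= 0) return(1)
  i <- x:n
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log(1 - p0)))
}

# elbow search by explicit residual-standard-error enumeration
oracle_elbow <- function(k, gof) {
  n <- length(k)
  best_k <- NA; best_rse <- Inf
  for (b in k[2:(n - 1)]) {
    X <- cbind(1, k, pmax(k - b, 0))
    r <- stats::lsfit(X, gof, intercept = FALSE)$residuals
    rse <- sqrt(sum(r^2) / (n - 3))
    if (rse < best_rse - 1e-10) { best_rse <- rse; best_k <- b }
  }
  best_k
}
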