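# Shared fixtures and independent brute-force oracles. The oracles are kept
# deliberately naive (explicit loops over animals and loci) so they share no
# code path with the package implementations they check.

# dosage matrix with every column guaranteed polymorphic
rand_dosages <- function(n, m, p = NULL, seed = NULL) {
  with_seed(seed, {
    p <- p %||% runif(m, 0.1, 0.5)
    p <- rep_len(p, m)
    X <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      repeat {
        x <- rbinom(n, 2L, p[j])
        if (length(unique(x)) > 1L) break
      }
      X[, j] <- x
    }
    X
  })
}

# wrap a dosage matrix into a panel on one chromosome, evenly spaced
panel_from_matrix <- function(X, spacing = 1000L, chrom = NULL, pos = NULL,
                              panels = NULL) {
  m <- ncol(X)
  chrom <- chrom %||% rep(1L, m)
  if (is.null(pos)) {  # chrom assumed sorted when defaulted
    pos <- unlist(lapply(split(rep(spacing, m), chrom), cumsum), use.names = FALSE)
  }
  map <- data.frame(snp_id = sprintf("s%04d", seq_len(m)), chrom = chrom,
                    pos = as.integer(pos), target_freq = NA_real_,
                    stringsAsFactors = FALSE)
  colnames(X) <- map$snp_id
  genotype_panel(X, map, panels = panels)
}

oracle_grm_vanraden <- function(X) {
  n <- nrow(X); m <- ncol(X)
  p <- numeric(m)
  for (j in seq_len(m)) p[j] <- sum(X[, j]) / (2 * n)
  denom <- 0
  for (j in seq_len(m)) denom <- denom + 2 * p[j] * (1 - p[j])
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (j in seq_len(m)) s <- s + (X[i, j] - 2 * p[j]) * (X[k, j] - 2 * p[j])
    G[i, k] <- s / denom
  }
  G
}

oracle_grm_yang <- function(X) {
  n <- nrow(X); m <- ncol(X)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (j in seq_len(m)) {
      p <- sum(X[, j]) / (2 * n)
      s <- s + (X[i, j] - 2 * p) * (X[k, j] - 2 * p) / (2 * p * (1 - p))
    }
    G[i, k] <- s / m
  }
  G
}

oracle_grm_speed <- function(X, k) {
  n <- nrow(X); m <- ncol(X)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (l in seq_len(n)) {
    s <- 0
    for (j in seq_len(m)) {
      p <- sum(X[, j]) / (2 * n)
      zi <- (X[i, j] - 2 * p) / sqrt(2 * p * (1 - p))
      zl <- (X[l, j] - 2 * p) / sqrt(2 * p * (1 - p))
      s <- s + k[j] * zi * zl
    }
    G[i, l] <- s / sum(k)
  }
  G
}

# a mid-sized LD panel with biased sparse arrays, reused by the slower
# validation-style tests (built once per test file that asks for it)
build_study_panel <- function(n_animals = 400, n_snps = 2000, n_sparse50 = 450,
                              n_sparse7 = 90, seed = 421) {
  map <- snp_map(n_snps, n_chrom = 5, spacing_bp = 4000, seed = seed)
  pan <- simulate_genotypes(map, n_animals, family = family_spec(),
                            ld_decay = 5e4, seed = seed + 1)
  assign_marker_panels(pan, n_sparse7, n_sparse50, high_maf_bias = 1,
                       seed = seed + 2)
}
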