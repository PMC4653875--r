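# QTL sampling by MAF category, substitution-effect models, variance
# standardisation, and trait simulation. Throughout, the trait is scaled so
# that total phenotypic variance is 100 and Var(TBV) = 100 * h2 holds exactly
# in-sample (population-variance convention, denominator n).

#' MAF category bounds
#'
#' The three categories used to stratify causal loci: `low` is
#' `0.01 <= MAF <= 0.05`, `high` is `0.05 < MAF <= 0.5` and `all` is their
#' union. The boundary 0.05 belongs to `low`.
#'
#' @param name One of `"all"`, `"high"`, `"low"`.
#' @return List with `name`, `lo`, `hi` and logical `lo_open` (whether the
#'   lower bound is exclusive).
#' @export
maf_category <- function(name = c("all", "high", "low")) {
  name <- match.arg(name)
  switch(name,
    all = list(name = "all", lo = 0.01, hi = 0.5, lo_open = FALSE),
    low = list(name = "low", lo = 0.01, hi = 0.05, lo_open = FALSE),
    high = list(name = "high", lo = 0.05, hi = 0.5, lo_open = TRUE)
  )
}

maf_in_category <- function(maf, cat) {
  if (cat$lo_open) maf > cat$lo & maf <= cat$hi else maf >= cat$lo & maf <= cat$hi
}

#' Integral shares of the U-shaped density below and above a MAF split
#'
#' For `f(p) = 1/(p(1-p))` truncated to `[lo, hi]`, returns the shares of mass
#' in `[lo, split]` and `(split, hi]` via the closed-form antiderivative
#' `ln(p/(1-p))`. With the defaults this yields the 0.36:0.64 low/high split
#' used when drawing causal loci of mixed frequency.
#'
#' @param lo,split,hi Bounds with `0 < lo < split < hi < 1`.
#' @return Named numeric vector `c(low = ..., high = ...)` summing to 1.
#' @examples
#' round(ushape_interval_shares(), 2)  # 0.36, 0.64
#' @export
ushape_interval_shares <- function(lo = 0.01, split = 0.05, hi = 0.5) {
  if (!(lo > 0 && lo < split && split <= hi && hi < 1)) {
    stop("need 0 < lo < split <= hi < 1", call. = FALSE)
  }
  total <- stats::qlogis(hi) - stats::qlogis(lo)
  low <- (stats::qlogis(split) - stats::qlogis(lo)) / total
  c(low = low, high = 1 - low)
}

#' Sample QTLs from the candidate pool of a panel
#'
#' Draws `n_qtl` loci uniformly without replacement from the candidate-QTL
#' pool (SNPs not on any sparse marker panel) whose observed MAF falls in the
#' requested category. For `category = "all"` the draw is stratified:
#' `round_half_up(0.36 * n_qtl)` loci from the low-MAF range and the remainder
#' from the high range, the deterministic realisation of the U-shape integral
#' ratio (0.36:0.64 at two decimals).
#'
#' @param panel A `genotype_panel`.
#' @param category `"all"`, `"high"` or `"low"`.
#' @param n_qtl Number of causal loci.
#' @param seed Optional integer seed.
#' @return An object of class `qtl_set`: SNP ids, column indices, allele
#'   frequencies `p`, effects `b` (zero until [draw_effects()]), the category
#'   and (after standardisation) `sigma_g2`.
#' @export
sample_qtls <- function(panel, category = "all", n_qtl, seed = NULL) {
  cat <- maf_category(category)
  pool_ids <- candidate_qtl_ids(panel)
  if (length(pool_ids) == 0) stop("candidate-QTL pool is empty", call. = FALSE)
  p_all <- allele_frequencies(panel)
  maf <- pmin(p_all, 1 - p_all)
  names(maf) <- as.character(panel$map$snp_id)
  pool_maf <- maf[pool_ids]
  pick <- function(ids, k, what) {
    if (length(ids) < k) {
      stop(sprintf("candidate pool too small for category '%s': need %d, have %d",
                   what, k, length(ids)), call. = FALSE)
    }
    if (k == 0) character() else if (length(ids) == k) ids else sample(ids, k)
  }
  with_seed(seed, {
    if (cat$name == "all") {
      shares <- round(ushape_interval_shares(cat$lo, 0.05, cat$hi), 2)
      n_low <- round_half_up(shares[["low"]] * n_qtl)
      low_ids <- pool_ids[maf_in_category(pool_maf, maf_category("low"))]
      high_ids <- pool_ids[maf_in_category(pool_maf, maf_category("high"))]
      ids <- c(pick(low_ids, n_low, "low"), pick(high_ids, n_qtl - n_low, "high"))
    } else {
      ids <- pick(pool_ids[maf_in_category(pool_maf, cat)], n_qtl, cat$name)
    }
    idx <- match(ids, as.character(panel$map$snp_id))
    structure(list(
      snp_id = ids, index = idx, p = unname(p_all[idx]),
      b = rep(0, length(ids)), category = cat$name,
      effect_model = NA_character_, sigma_g2 = NA_real_
    ), class = "qtl_set")
  })
}

#' @export
print.qtl_set <- function(x, ...) {
  cat(sprintf("qtl_set: %d QTLs, category '%s', effects '%s', sigma_g2 = %s\n",
              length(x$snp_id), x$category, x$effect_model,
              format(x$sigma_g2)))
  invisible(x)
}

#' Draw QTL substitution effects
#'
#' Two effect architectures. `"gamma"`: |b| i.i.d. Gamma(shape, scale),
#' independent of allele frequency. `"equal_variance"`:
#' `|b| = 1/sqrt(2 p (1-p))`, so each locus contributes equal additive
#' variance `2p(1-p)b^2 = 1` under linkage equilibrium — low-MAF loci get
#' proportionally larger effects. Signs are i.i.d. +/-1 in both models.
#'
#' @param qtls A `qtl_set` with known allele frequencies.
#' @param model `"gamma"` or `"equal_variance"`.
#' @param shape,scale Gamma parameters (mean = shape * scale).
#' @param seed Optional integer seed.
#' @return The `qtl_set` with `b` filled in and `effect_model` set.
#' @export
draw_effects <- function(qtls, model = c("equal_variance", "gamma"),
                         shape = 0.4, scale = 1.66, seed = NULL) {
  model <- match.arg(model)
  m <- length(qtls$snp_id)
  with_seed(seed, {
    mag <- switch(model,
      gamma = stats::rgamma(m, shape = shape, scale = scale),
      equal_variance = 1 / sqrt(2 * qtls$p * (1 - qtls$p))
    )
    qtls$b <- mag * sample(c(-1, 1), m, replace = TRUE)
    qtls$effect_model <- model
    qtls
  })
}

#' Standardise effects to a target genetic variance
#'
#' Multiplies every effect by one scalar so that the population variance of
#' TBV over the panel's animals equals `100 * h2` exactly (phenotypic variance
#' is later completed to 100 by the residual). The empirical realised-genotype
#' variance is used, not the expectation under HWE, so the identity holds
#' in-sample; rescaling is idempotent.
#'
#' @param qtls A `qtl_set` with effects drawn.
#' @param panel The `genotype_panel` the QTLs index into.
#' @param h2 Target QTL heritability in (0, 1).
#' @return The `qtl_set` with scaled `b` and `sigma_g2 = 100 * h2`.
#' @export
standardize_effects <- function(qtls, panel, h2) {
  if (!(h2 > 0 && h2 < 1)) stop("`h2` must lie in (0, 1)", call. = FALSE)
  tbv <- compute_tbv(panel, qtls)
  v0 <- pop_var(tbv)
  if (v0 <= 0) stop("TBV variance is zero before scaling; effects degenerate",
                    call. = FALSE)
  qtls$b <- qtls$b * sqrt(100 * h2 / v0)
  qtls$sigma_g2 <- 100 * h2
  qtls
}

#' True breeding values
#'
#' `tbv_i = sum_j x_ij b_j` over the QTL columns.
#'
#' @param panel A `genotype_panel` with complete dosages at the QTL columns.
#' @param qtls A `qtl_set`.
#' @return Named numeric vector of per-animal TBVs.
#' @export
compute_tbv <- function(panel, qtls) {
  X <- panel$dosages[, qtls$index, drop = FALSE]
  if (anyNA(X)) stop("missing dosages at QTL columns", call. = FALSE)
  drop(X %*% qtls$b)
}

#' Simulate phenotypes from true breeding values
#'
#' `y_i = tbv_i + e_i` with `e_i` i.i.d. Normal(0, sigma_g2 (1/h2 - 1)), where
#' `sigma_g2` is the (population) variance of the supplied TBVs. With
#' standardised effects this puts total phenotypic variance at 100 for every
#' heritability setting.
#'
#' @param tbv Per-animal true breeding values (standardised scale).
#' @param h2 QTL heritability in (0, 1).
#' @param seed Optional integer seed.
#' @return Object of class `trait_simulation`: `tbv`, `y`, `h2_true`,
#'   `sigma_g2`, `sigma_e2`.
#' @export
simulate_phenotypes <- function(tbv, h2, seed = NULL) {
  if (!(h2 > 0 && h2 < 1)) stop("`h2` must lie in (0, 1)", call. = FALSE)
  with_seed(seed, {
    sigma_g2 <- pop_var(tbv)
    sigma_e2 <- sigma_g2 * (1 / h2 - 1)
    e <- stats::rnorm(length(tbv), 0, sqrt(sigma_e2))
    structure(list(tbv = tbv, y = tbv + e, h2_true = h2,
                   sigma_g2 = sigma_g2, sigma_e2 = sigma_e2),
              class = "trait_simulation")
  })
}

#' @export
print.trait_simulation <- function(x, ...) {
  cat(sprintf(
    "trait_simulation: n = %d, h2 = %.2f, sigma_g2 = %.2f, sigma_e2 = %.2f\n",
    length(x$y), x$h2_true, x$sigma_g2, x$sigma_e2))
  invisible(x)
}

#' Write a QTL table as TSV
#' @param qtls A `qtl_set`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_qtl_table <- function(qtls, path) {
  utils::write.table(
    data.frame(snp_id = qtls$snp_id, p = qtls$p, b = qtls$b,
               category = qtls$category),
    path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write a simulated trait as TSV (animal_id, tbv, y)
#' @param trait A `trait_simulation`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_trait_table <- function(trait, path) {
  ids <- names(trait$tbv) %||% as.character(seq_along(trait$tbv))
  utils::write.table(
    data.frame(animal_id = ids, tbv = trait$tbv, y = trait$y),
    path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
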