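# Synthetic breeding population: LD-structured genotypes with half-sib family
# structure, U-shaped allele-frequency spectra on the dense panel and
# high-MAF-biased sparse marker panels, plus the QC steps applied to the real
# data the design emulates (MAF, call rate, HWE, close-relative exclusion).

#' Sample allele frequencies from the truncated U-shaped density
#'
#' Draws i.i.d. frequencies from `f(p) proportional to 1/(p(1-p))` truncated to
#' `[lo, hi]`, the classical spectrum of allele frequencies contributing
#' additive variance. Sampling is by inverse CDF using the closed-form
#' antiderivative `ln(p/(1-p))` (the logit), so draws are exact.
#'
#' @param n Number of draws.
#' @param lo,hi Truncation bounds, `0 < lo < hi <= 0.5` (equal bounds allowed
#'   as a degenerate point mass).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` frequencies in `[lo, hi]`.
#' @examples
#' p <- sample_ushape_frequencies(1000, 0.01, 0.5, seed = 1)
#' mean(p <= 0.05)  # about 0.36 of the mass is below 0.05
#' @export
sample_ushape_frequencies <- function(n, lo = 0.01, hi = 0.5, seed = NULL) {
  if (!(n >= 1)) stop("`n` must be >= 1", call. = FALSE)
  if (!(lo > 0 && lo <= hi && hi <= 0.5)) {
    stop("bounds must satisfy 0 < lo <= hi <= 0.5", call. = FALSE)
  }
  with_seed(seed, {
    if (lo == hi) return(rep(lo, n))
    a <- stats::qlogis(lo)
    b <- stats::qlogis(hi)
    stats::plogis(a + stats::runif(n) * (b - a))
  })
}

#' Half-sib family specification
#'
#' Progeny-per-sire law used by [simulate_genotypes()]: a geometric
#' distribution on 1, 2, ... truncated at `max_progeny`, with success
#' probability `1/mean_progeny` so the untruncated mean equals `mean_progeny`.
#' The defaults target the structure of the study population (mean 3.1,
#' maximum 24 progeny per sire).
#'
#' @param mean_progeny Target mean progeny per sire.
#' @param max_progeny Hard maximum progeny per sire.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(mean_progeny = 3.1, max_progeny = 24L) {
  stopifnot(mean_progeny >= 1, max_progeny >= 1)
  structure(list(mean_progeny = mean_progeny, max_progeny = as.integer(max_progeny)),
            class = "family_spec")
}

#' Build a SNP map with U-shaped frequencies
#'
#' Convenience constructor for the per-SNP map consumed by
#' [simulate_genotypes()]: SNPs are laid out on `n_chrom` chromosomes with
#' exponentially distributed inter-SNP gaps (mean `spacing_bp`), and assigned
#' target allele frequencies drawn from the truncated U-shaped density unless
#' `freqs` is supplied.
#'
#' @param n_snps Total number of SNPs.
#' @param n_chrom Number of chromosomes (SNPs split as evenly as possible).
#' @param spacing_bp Mean gap between adjacent SNPs in base pairs.
#' @param freqs Optional vector of target frequencies in (0, 0.5], recycled.
#' @param lo,hi U-shape truncation bounds when `freqs` is NULL.
#' @param seed Optional integer seed.
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `target_freq`;
#'   positions strictly increasing within chromosome, 1-based.
#' @export
snp_map <- function(n_snps, n_chrom = 5L, spacing_bp = 4000, freqs = NULL,
                    lo = 0.01, hi = 0.5, seed = NULL) {
  stopifnot(n_snps >= 1, n_chrom >= 1, spacing_bp > 0)
  with_seed(seed, {
    chrom <- sort(rep_len(seq_len(n_chrom), n_snps))
    gaps <- pmax(1, round(stats::rexp(n_snps, rate = 1 / spacing_bp)))
    pos <- unlist(lapply(split(gaps, chrom), cumsum), use.names = FALSE)
    tf <- if (is.null(freqs)) {
      sample_ushape_frequencies(n_snps, lo, hi)
    } else {
      rep_len(freqs, n_snps)
    }
    data.frame(
      snp_id = sprintf("snp%0*d", nchar(n_snps), seq_len(n_snps)),
      chrom = chrom, pos = as.integer(pos), target_freq = tf,
      stringsAsFactors = FALSE
    )
  })
}

#' Genotype panel container
#'
#' Bundles a dosage matrix (animals x SNPs, entries 0/1/2 counting the second
#' allele, `NA` for missing) with its SNP map, sparse-panel tags and sire
#' assignments. The dense panel always comprises every SNP; the `sparse7` tag
#' set is nested inside `sparse50`.
#'
#' @param dosages Integer matrix, rows = animals, columns = SNPs. Row and
#'   column names are taken as animal and SNP ids.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos` (strictly
#'   increasing within chromosome) and optionally `target_freq`.
#' @param panels Named list with character vectors `sparse7`, `sparse50` of
#'   SNP ids; defaults to empty tags.
#' @param sire_of Named character vector mapping animal id to sire id
#'   (`NA` for founders or unknown).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, map, panels = NULL, sire_of = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("id%0*d", nchar(nrow(dosages)), seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) colnames(dosages) <- map$snp_id
  stopifnot(is.data.frame(map), all(c("snp_id", "chrom", "pos") %in% names(map)))
  if (ncol(dosages) != nrow(map)) stop("dosage columns != map rows", call. = FALSE)
  if (!identical(colnames(dosages), as.character(map$snp_id))) {
    stop("dosage column names must match map$snp_id in order", call. = FALSE)
  }
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("map positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
    }
  }
  if (any(colMeans(is.na(dosages)) >= 1)) {
    stop("a SNP has no observed calls", call. = FALSE)
  }
  panels <- panels %||% list(sparse7 = character(), sparse50 = character())
  panels$sparse7 <- as.character(panels$sparse7 %||% character())
  panels$sparse50 <- as.character(panels$sparse50 %||% character())
  if (!all(panels$sparse7 %in% panels$sparse50)) {
    stop("panel nesting violated: sparse7 must be a subset of sparse50", call. = FALSE)
  }
  if (!all(panels$sparse50 %in% map$snp_id)) {
    stop("sparse50 tags name unknown SNPs", call. = FALSE)
  }
  if (is.null(sire_of)) {
    sire_of <- stats::setNames(rep(NA_character_, nrow(dosages)), rownames(dosages))
  }
  stopifnot(length(sire_of) == nrow(dosages))
  structure(
    list(dosages = dosages, map = map,
         panels = panels[c("sparse7", "sparse50")],
         sire_of = sire_of),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d animals x %d SNPs (%d chrom); sparse7 %d, sparse50 %d, missing %.2f%%\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom)),
    length(x$panels$sparse7), length(x$panels$sparse50),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' Animal ids of a panel
#' @param panel A `genotype_panel`.
#' @return Character vector of animal ids.
#' @export
animal_ids <- function(panel) rownames(panel$dosages)

#' SNP ids belonging to a named marker panel
#'
#' `"dense"` is every SNP; `"sparse7"`/`"sparse50"` are the tag sets. The
#' error-injected densities (`"sparse7_err"`, `"sparse50_err"`) use the dense
#' SNP set — they model dense genotypes recovered from a sparse array, whose
#' dosage errors are handled by [inject_genotype_errors()], not by the id set.
#'
#' @param panel A `genotype_panel`.
#' @param name One of `"dense"`, `"sparse7"`, `"sparse50"`, `"sparse7_err"`,
#'   `"sparse50_err"`.
#' @return Character vector of SNP ids.
#' @export
marker_ids <- function(panel, name = "dense") {
  switch(match.arg(name, c("dense", "sparse7", "sparse50", "sparse7_err", "sparse50_err")),
    dense = ,
    sparse7_err = ,
    sparse50_err = as.character(panel$map$snp_id),
    sparse7 = panel$panels$sparse7,
    sparse50 = panel$panels$sparse50
  )
}

#' Candidate-QTL pool of a panel
#'
#' SNPs present on the dense panel but not designated as sparse-array markers;
#' causal loci are sampled from this pool so that sparse marker panels never
#' contain a QTL.
#'
#' @param panel A `genotype_panel`.
#' @return Character vector of SNP ids.
#' @export
candidate_qtl_ids <- function(panel) {
  setdiff(as.character(panel$map$snp_id), panel$panels$sparse50)
}

# progeny counts per sire: truncated geometric, drawn until n animals covered
draw_family_sizes <- function(n_animals, family) {
  p <- 1 / family$mean_progeny
  sizes <- integer(0)
  while (sum(sizes) < n_animals) {
    k <- stats::rgeom(ceiling(n_animals / family$mean_progeny) + 10L, p) + 1L
    sizes <- c(sizes, pmin(k, family$max_progeny))
  }
  last <- which(cumsum(sizes) >= n_animals)[1L]
  sizes <- sizes[seq_len(last)]
  sizes[last] <- sizes[last] - (sum(sizes) - n_animals)
  sizes[sizes > 0]
}

#' Simulate LD-structured, family-structured genotypes
#'
#' Haplotypes are generated from a latent-Gaussian copula: along each
#' chromosome a stationary first-order Gaussian process with adjacent-SNP
#' correlation `exp(-gap_bp / ld_decay)` is thresholded at the per-SNP normal
#' quantile of `target_freq`, so each SNP's marginal allele frequency matches
#' its target while adjacent SNPs are in LD that decays with distance. With a
#' `family_spec`, unobserved sires are simulated first; each animal inherits
#' one of its sire's two haplotypes per chromosome (no within-chromosome
#' recombination) plus one fresh population haplotype, giving half-sib
#' families with expected genomic relationship ~0.25. With `family = NULL`
#' animals are unrelated.
#'
#' @param map SNP map as produced by [snp_map()]; must be position-sorted.
#' @param n_animals Number of animals (>= 2).
#' @param family A [family_spec()] or `NULL` for unrelated animals.
#' @param ld_decay Correlation length in bp; `0` gives independent SNPs.
#' @param seed Optional integer seed.
#' @return A [genotype_panel()] with complete (no missing) dosages.
#' @export
simulate_genotypes <- function(map, n_animals, family = family_spec(),
                               ld_decay = 5e4, seed = NULL) {
  if (n_animals < 2) stop("`n_animals` must be >= 2", call. = FALSE)
  stopifnot(is.data.frame(map), all(c("snp_id", "chrom", "pos", "target_freq") %in% names(map)))
  for (ch in unique(map$chrom)) {
    if (any(diff(map$pos[map$chrom == ch]) <= 0)) {
      stop("map must be position-sorted within chromosome", call. = FALSE)
    }
  }
  stopifnot(all(map$target_freq > 0), all(map$target_freq <= 0.5))
  with_seed(seed, {
    m <- nrow(map)
    if (is.null(family)) {
      sizes <- rep(1L, n_animals)  # one "sire" per animal, never shared
    } else {
      sizes <- draw_family_sizes(n_animals, family)
    }
    n_sires <- length(sizes)
    sire_of_idx <- rep(seq_len(n_sires), sizes)
    n_gam <- 2L * n_sires + n_animals

    # latent first-order process, vectorised across gametes
    gaps <- c(Inf, diff(map$pos))
    gaps[c(TRUE, diff(map$chrom) != 0)] <- Inf
    rho <- if (ld_decay > 0) exp(-gaps / ld_decay) else rep(0, m)
    innov_sd <- sqrt(1 - rho^2)
    z <- matrix(0, n_gam, m)
    z[, 1L] <- stats::rnorm(n_gam)
    for (j in 2:m) {
      z[, j] <- rho[j] * z[, j - 1L] + innov_sd[j] * stats::rnorm(n_gam)
    }
    thr <- stats::qnorm(map$target_freq)
    alleles <- sweep(z, 2L, thr, "<")
    storage.mode(alleles) <- "integer"

    sire_gam <- matrix(seq_len(2L * n_sires), nrow = 2L)  # columns = sires
    n_chrom <- length(unique(map$chrom))
    chrom_of <- match(map$chrom, unique(map$chrom))
    # transmitted gamete: per animal per chromosome pick one sire haplotype
    pick <- matrix(sample(c(1L, 2L), n_animals * n_chrom, replace = TRUE),
                   n_animals, n_chrom)
    dos <- matrix(0L, n_animals, m)
    for (ch in seq_len(n_chrom)) {
      cols <- which(chrom_of == ch)
      gidx <- sire_gam[cbind(pick[, ch], sire_of_idx)]
      dos[, cols] <- alleles[gidx, cols, drop = FALSE]
    }
    pop_gam <- 2L * n_sires + seq_len(n_animals)
    dos <- dos + alleles[pop_gam, , drop = FALSE]

    ids <- sprintf("id%0*d", nchar(n_animals), seq_len(n_animals))
    rownames(dos) <- ids
    colnames(dos) <- map$snp_id
    sire_ids <- sprintf("sire%0*d", nchar(n_sires), seq_len(n_sires))
    sire_of <- stats::setNames(sire_ids[sire_of_idx], ids)
    if (is.null(family)) sire_of[] <- NA_character_
    genotype_panel(dos, map, sire_of = sire_of)
  })
}

#' Designate sparse marker panels with a high-MAF bias
#'
#' Tags `n_sparse50` SNPs as the mid-density array and, nested inside it,
#' `n_sparse7` SNPs as the low-density array. Sampling weights are
#' `MAF^high_maf_bias` (observed MAF), reproducing the high-MAF skew of
#' commercial genotyping arrays; `high_maf_bias = 0` samples uniformly. All
#' SNPs not tagged by the mid-density array form the candidate-QTL pool.
#'
#' @param panel A `genotype_panel`.
#' @param n_sparse7,n_sparse50 Panel sizes, `n_sparse7 <= n_sparse50 <= m`.
#' @param high_maf_bias Non-negative exponent on MAF in the sampling weight.
#' @param seed Optional integer seed.
#' @return The panel with updated tags.
#' @export
assign_marker_panels <- function(panel, n_sparse7, n_sparse50,
                                 high_maf_bias = 1, seed = NULL) {
  m <- nrow(panel$map)
  if (!(n_sparse7 <= n_sparse50 && n_sparse50 <= m)) {
    stop("need n_sparse7 <= n_sparse50 <= number of SNPs", call. = FALSE)
  }
  stopifnot(high_maf_bias >= 0)
  with_seed(seed, {
    p <- allele_frequencies(panel)
    maf <- pmin(p, 1 - p)
    w <- if (high_maf_bias == 0) rep(1, m) else maf^high_maf_bias
    ids <- as.character(panel$map$snp_id)
    s50 <- weighted_sample_norep(ids, n_sparse50, w)
    w7 <- w[match(s50, ids)]
    s7 <- weighted_sample_norep(s50, n_sparse7, w7)
    panel$panels$sparse50 <- sort(s50)
    panel$panels$sparse7 <- sort(s7)
    panel
  })
}

#' Inject calibrated genotype errors
#'
#' Stand-in for imputation noise: for each SNP, a fraction `1 - target_correlation`
#' of animals has its dosage replaced by a fresh Binomial(2, p_hat) draw at the
#' SNP's observed allele frequency. The replacement is independent of the true
#' dosage, so the expected per-SNP Pearson correlation between original and
#' perturbed columns equals `target_correlation` (to first order). Dosages
#' remain in 0/1/2; missing entries are untouched.
#'
#' @param panel A `genotype_panel`.
#' @param target_correlation Value in (0, 1]; `1` returns the panel unchanged.
#' @param seed Optional integer seed.
#' @return A `genotype_panel` with perturbed dosages.
#' @export
inject_genotype_errors <- function(panel, target_correlation, seed = NULL) {
  if (!(target_correlation > 0 && target_correlation <= 1)) {
    stop("`target_correlation` must lie in (0, 1]", call. = FALSE)
  }
  if (target_correlation == 1) return(panel)
  with_seed(seed, {
    dos <- panel$dosages
    n <- nrow(dos)
    p <- allele_frequencies(panel)
    theta <- 1 - target_correlation
    for (j in seq_len(ncol(dos))) {
      hit <- stats::runif(n) < theta & !is.na(dos[, j])
      k <- sum(hit)
      if (k > 0) dos[hit, j] <- stats::rbinom(k, 2L, p[j])
    }
    panel$dosages <- dos
    panel
  })
}

# 1-df goodness-of-fit chi-square of genotype counts against HWE proportions
hwe_pvalue <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((counts - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' SNP quality control
#'
#' Removes SNPs failing, in order, MAF < `maf_min`, call rate < `call_rate_min`,
#' or a Hardy-Weinberg 1-df chi-square goodness-of-fit test with p-value below
#' `hwe_alpha`. Only the first failing rule is recorded per SNP. Filtering is
#' idempotent: running it on its own output removes nothing.
#'
#' @param panel A `genotype_panel`.
#' @param maf_min,call_rate_min,hwe_alpha Thresholds (defaults match the
#'   exclusion criteria applied to the study genotypes).
#' @return List with elements `panel` (filtered) and `report` (a `qc_report`:
#'   data.frames `snps` with columns `snp_id`, `reason` and `animals`).
#' @export
qc_filter <- function(panel, maf_min = 0.01, call_rate_min = 0.95,
                      hwe_alpha = 0.001) {
  dos <- panel$dosages
  if (ncol(dos) == 0) stop("panel has no SNPs", call. = FALSE)
  call_rate <- colMeans(!is.na(dos))
  p <- allele_frequencies(panel)
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    x <- dos[, j]
    hwe_pvalue(c(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                 sum(x == 2L, na.rm = TRUE)))
  }, numeric(1))
  reason <- rep(NA_character_, ncol(dos))
  reason[is.na(reason) & maf < maf_min] <- "maf"
  reason[is.na(reason) & call_rate < call_rate_min] <- "call_rate"
  reason[is.na(reason) & !is.na(hwe_p) & hwe_p < hwe_alpha] <- "hwe"
  drop <- !is.na(reason)
  if (all(drop)) stop("QC removed every SNP", call. = FALSE)
  report <- structure(list(
    snps = data.frame(snp_id = colnames(dos)[drop], reason = reason[drop],
                      stringsAsFactors = FALSE),
    animals = data.frame(animal_id = character(), max_kinship = numeric(),
                         stringsAsFactors = FALSE)
  ), class = "qc_report")
  keep <- which(!drop)
  out <- panel
  out$dosages <- dos[, keep, drop = FALSE]
  out$map <- panel$map[keep, , drop = FALSE]
  out$panels$sparse50 <- intersect(panel$panels$sparse50, colnames(out$dosages))
  out$panels$sparse7 <- intersect(panel$panels$sparse7, out$panels$sparse50)
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d SNPs removed (%s); %d animals removed\n",
              nrow(x$snps),
              paste(sprintf("%s=%d", names(table(x$snps$reason)),
                            as.integer(table(x$snps$reason))), collapse = ", "),
              nrow(x$animals)))
  invisible(x)
}

#' Exclude close relatives by genomic relationship
#'
#' Greedily removes animals whose genomic relationship with any other animal
#' exceeds `cutoff` in absolute value: at each step the animal involved in the
#' most violations is dropped (ties broken by id order) until no off-diagonal
#' element exceeds the cutoff.
#'
#' @param panel A `genotype_panel`.
#' @param grm A [build_grm_vanraden()]-style `grm` over the panel's animals.
#' @param cutoff Positive threshold on |off-diagonal| (default 0.4).
#' @return List with `panel` (animals removed) and `report` (a `qc_report`
#'   whose `animals` table carries each removal's largest offending kinship).
#' @export
exclude_close_relatives <- function(panel, grm, cutoff = 0.4) {
  if (!(cutoff > 0)) stop("`cutoff` must be positive", call. = FALSE)
  G <- grm$matrix
  ids <- animal_ids(panel)
  stopifnot(nrow(G) == length(ids))
  dimnames(G) <- list(ids, ids)
  A <- abs(G); diag(A) <- 0
  removed <- character(); offending <- numeric()
  while (TRUE) {
    viol <- rowSums(A > cutoff)
    if (max(viol) == 0) break
    worst <- which(viol == max(viol))[1L]  # ids are in order, first = tie-break
    removed <- c(removed, rownames(A)[worst])
    offending <- c(offending, max(A[worst, ]))
    A <- A[-worst, -worst, drop = FALSE]
  }
  report <- structure(list(
    snps = data.frame(snp_id = character(), reason = character(),
                      stringsAsFactors = FALSE),
    animals = data.frame(animal_id = removed, max_kinship = offending,
                         stringsAsFactors = FALSE)
  ), class = "qc_report")
  keep <- setdiff(ids, removed)
  out <- panel
  out$dosages <- panel$dosages[keep, , drop = FALSE]
  out$sire_of <- panel$sire_of[keep]
  list(panel = out, report = report)
}
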