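# Genomic relationship matrices. Three builders are provided:
#   vanraden:  G = Z Z' / (2 * sum_j p_j (1 - p_j)),  z_ij = x_ij - 2 p_j
#   yang:      G = Zbar Zbar' / m, zbar_ij = z_ij / sqrt(2 p_j (1 - p_j))
#   speed:     G = W W' / sum_j k_j, w_ij = sqrt(k_j) zbar_ij
# plus the MAF-partitioned Yang pair used by the two-component model.
# Allele frequencies are always computed on the full analysis sample.

#' Allele frequencies of the second allele
#'
#' `p_j` = mean dosage / 2 over non-missing calls, on the full analysis set.
#'
#' @param panel A `genotype_panel`.
#' @param snp_ids SNP ids to use; default all.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(panel, snp_ids = NULL) {
  ids <- as.character(panel$map$snp_id)
  use <- snp_ids %||% ids
  if (length(use) == 0) stop("empty SNP subset", call. = FALSE)
  idx <- match(use, ids)
  if (anyNA(idx)) stop("unknown SNP ids in subset", call. = FALSE)
  p <- colMeans(panel$dosages[, idx, drop = FALSE], na.rm = TRUE) / 2
  stats::setNames(p, use)
}

# centered dosage matrix; missing dosages mean-imputed (i.e. centered to 0)
centered_dosages <- function(panel, snp_ids, p) {
  idx <- match(snp_ids, as.character(panel$map$snp_id))
  Z <- sweep(panel$dosages[, idx, drop = FALSE], 2L, 2 * p, "-")
  Z[is.na(Z)] <- 0
  Z
}

new_grm <- function(matrix, kind, snp_ids, weights = NULL, jitter = 0) {
  dimnames(matrix) <- NULL
  structure(list(matrix = matrix, kind = kind, snp_ids = snp_ids,
                 weights = weights %||% rep(1, length(snp_ids)),
                 jitter = jitter),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm (%s): %d x %d from %d SNPs, jitter %g\n",
              x$kind, nrow(x$matrix), ncol(x$matrix), length(x$snp_ids),
              x$jitter))
  invisible(x)
}

check_polymorphic <- function(p, snp_ids, all_required) {
  mono <- p <= 0 | p >= 1
  if (all(mono)) stop("all SNPs in subset are monomorphic", call. = FALSE)
  if (all_required && any(mono)) {
    stop("monomorphic SNPs in subset: ", paste(snp_ids[mono], collapse = ", "),
         call. = FALSE)
  }
  mono
}

#' VanRaden genomic relationship matrix
#'
#' Centers dosages by twice the allele frequency and scales by the summed
#' heterozygosity, `2 sum_j p_j(1-p_j)`. Monomorphic SNPs contribute zero to
#' both numerator and denominator.
#'
#' @param panel A `genotype_panel`.
#' @param snp_ids SNP subset (default all).
#' @return A `grm` of kind `"vanraden"`.
#' @export
build_grm_vanraden <- function(panel, snp_ids = NULL) {
  snp_ids <- snp_ids %||% as.character(panel$map$snp_id)
  p <- allele_frequencies(panel, snp_ids)
  check_polymorphic(p, snp_ids, all_required = FALSE)
  Z <- centered_dosages(panel, snp_ids, p)
  denom <- 2 * sum(p * (1 - p))
  new_grm(tcrossprod(Z) / denom, "vanraden", snp_ids)
}

#' Yang (allele-frequency standardised) genomic relationship matrix
#'
#' Each centered dosage is divided by its per-SNP standard deviation
#' `sqrt(2 p_j (1-p_j))` before the cross-product, which upweights rare
#' alleles relative to the VanRaden scaling; the matrix is divided by the SNP
#' count `m`. All subset SNPs must be polymorphic.
#'
#' @inheritParams build_grm_vanraden
#' @return A `grm` of kind `"yang"`.
#' @export
build_grm_yang <- function(panel, snp_ids = NULL) {
  snp_ids <- snp_ids %||% as.character(panel$map$snp_id)
  p <- allele_frequencies(panel, snp_ids)
  check_polymorphic(p, snp_ids, all_required = TRUE)
  Z <- centered_dosages(panel, snp_ids, p)
  Zbar <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  new_grm(tcrossprod(Zbar) / length(snp_ids), "yang", snp_ids)
}

#' LD-adjusted SNP weights
#'
#' Computes non-negative per-SNP weights `k_j` such that, within a sliding
#' physical window, the distance-damped sum of local squared correlations
#' times the weights is close to 1 for every SNP:
#' minimise `sum_j (sum_k d_jk r2_jk w_k - 1)^2` subject to `w >= 0`, with
#' `d_jk = exp(-ln(2) * gap_bp / decay_halflife_bp)` and `r2_jj = 1`. Exactly
#' duplicated SNPs thus share weight (a pair gets 0.5 each) while mutually
#' independent SNPs keep weight ~1, so `sum_j k_j` tracks the number of
#' effective loci. The non-negative least-squares problems are solved per
#' chromosome with a tiny ridge term that selects the minimum-norm solution
#' when the optimum is not unique. `passes = 2` re-solves on the
#' first-pass-weighted correlations (recommended for dense panels) and
#' returns the product of the two passes.
#'
#' @param panel A `genotype_panel`, position-sorted.
#' @param snp_ids SNP subset (default all).
#' @param window_bp Window half-width in bp within which r2 is computed.
#' @param decay_halflife_bp Distance at which the damping factor halves.
#' @param passes 1 or 2 solver passes.
#' @return Named numeric vector of non-negative weights.
#' @export
compute_ld_weights <- function(panel, snp_ids = NULL, window_bp = 1e6,
                               decay_halflife_bp = 125e3, passes = 1L) {
  snp_ids <- snp_ids %||% as.character(panel$map$snp_id)
  stopifnot(passes %in% c(1L, 2L), window_bp > 0, decay_halflife_bp > 0)
  idx <- match(snp_ids, as.character(panel$map$snp_id))
  if (anyNA(idx)) stop("unknown SNP ids", call. = FALSE)
  sub <- panel$map[idx, , drop = FALSE]
  for (ch in unique(sub$chrom)) {
    if (any(diff(sub$pos[sub$chrom == ch]) <= 0)) {
      stop("SNP subset must be position-sorted within chromosome", call. = FALSE)
    }
  }
  p <- allele_frequencies(panel, snp_ids)
  check_polymorphic(p, snp_ids, all_required = TRUE)
  Z <- scale(centered_dosages(panel, snp_ids, p))  # unit-variance columns
  w <- rep(NA_real_, length(snp_ids))
  for (ch in unique(sub$chrom)) {
    sel <- which(sub$chrom == ch)
    pos <- sub$pos[sel]
    mloc <- length(sel)
    A <- matrix(0, mloc, mloc)
    for (a in seq_len(mloc)) {
      near <- which(abs(pos - pos[a]) <= window_bp)
      r <- drop(crossprod(Z[, sel[near], drop = FALSE], Z[, sel[a]])) / (nrow(Z) - 1)
      d <- exp(-log(2) * abs(pos[near] - pos[a]) / decay_halflife_bp)
      A[a, near] <- d * r^2
      A[a, a] <- 1
    }
    w[sel] <- nnls_min_norm(A, rep(1, mloc))
    if (passes == 2L) {
      A2 <- sweep(A, 2L, w[sel], "*")
      v <- nnls_min_norm(A2, rep(1, mloc))
      w[sel] <- w[sel] * v
    }
  }
  stats::setNames(w, snp_ids)
}

# NNLS with a small ridge augmentation so ties resolve to the minimum-norm
# optimum (e.g. duplicated SNPs split weight evenly).
nnls_min_norm <- function(A, b, ridge = 1e-4) {
  n <- ncol(A)
  lam <- ridge * mean(diag(crossprod(A)))
  C <- rbind(A, diag(sqrt(lam), n))
  d <- c(b, rep(0, n))
  drop(pracma::lsqnonneg(C, d)$x)
}

#' LD-weighted (Speed-style) genomic relationship matrix
#'
#' Applies per-SNP weights to the allele-frequency-standardised dosages:
#' `w_ij = sqrt(k_j) zbar_ij`, `G = W W' / sum_j k_j`. With all weights 1 this
#' reduces exactly to the Yang matrix.
#'
#' @inheritParams build_grm_vanraden
#' @param weights Non-negative per-SNP weights `k_j` (length of the subset),
#'   e.g. from [compute_ld_weights()].
#' @return A `grm` of kind `"speed"`.
#' @export
build_grm_speed <- function(panel, snp_ids = NULL, weights) {
  snp_ids <- snp_ids %||% as.character(panel$map$snp_id)
  weights <- unname(weights)
  if (length(weights) != length(snp_ids)) {
    stop("`weights` length must match SNP subset", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) == 0) stop("all weights are zero", call. = FALSE)
  p <- allele_frequencies(panel, snp_ids)
  check_polymorphic(p, snp_ids, all_required = TRUE)
  Z <- centered_dosages(panel, snp_ids, p)
  Zbar <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  W <- sweep(Zbar, 2L, sqrt(weights), "*")
  new_grm(tcrossprod(W) / sum(weights), "speed", snp_ids, weights = weights)
}

#' MAF-partitioned pair of Yang GRMs
#'
#' Splits the SNP subset at `threshold` (the boundary MAF belongs to the low
#' stratum, matching the low-MAF category definition) and builds a Yang GRM
#' from each stratum, for the two-component variance model.
#'
#' @inheritParams build_grm_vanraden
#' @param threshold MAF split point (default 0.05).
#' @return List with `low` and `high`, each a `grm` of kind
#'   `"partition_low"` / `"partition_high"`.
#' @export
partition_grms_by_maf <- function(panel, snp_ids = NULL, threshold = 0.05) {
  snp_ids <- snp_ids %||% as.character(panel$map$snp_id)
  p <- allele_frequencies(panel, snp_ids)
  maf <- pmin(p, 1 - p)
  low_ids <- snp_ids[maf <= threshold]
  high_ids <- snp_ids[maf > threshold]
  if (length(low_ids) == 0) stop("empty low-MAF stratum", call. = FALSE)
  if (length(high_ids) == 0) stop("empty high-MAF stratum", call. = FALSE)
  gl <- build_grm_yang(panel, low_ids); gl$kind <- "partition_low"
  gh <- build_grm_yang(panel, high_ids); gh$kind <- "partition_high"
  list(low = gl, high = gh)
}

#' Add a diagonal jitter to a GRM
#'
#' Increments the diagonal by `jitter` (default 1e-5) to keep the matrix
#' safely positive definite in the mixed-model equations; off-diagonals are
#' untouched and every eigenvalue shifts by exactly `jitter`.
#'
#' @param grm A `grm`.
#' @param jitter Non-negative diagonal increment.
#' @return The regularised `grm` with its `jitter` field updated.
#' @export
regularize_grm <- function(grm, jitter = 1e-5) {
  stopifnot(inherits(grm, "grm"), jitter >= 0)
  diag(grm$matrix) <- diag(grm$matrix) + jitter
  grm$jitter <- grm$jitter + jitter
  grm
}

#' Restrict a GRM to a subset of animals
#'
#' @param grm A `grm` over the full animal set.
#' @param idx Row/column indices (or logical mask) of animals to keep.
#' @return A `grm` on the subset.
#' @export
subset_grm <- function(grm, idx) {
  grm$matrix <- grm$matrix[idx, idx, drop = FALSE]
  grm
}

#' Write a GRM in GCTA-style plain text
#'
#' `<prefix>.grm` holds the lower triangle as `i j n_snps value` (10
#' significant digits); `<prefix>.grm.id` holds the animal ids.
#'
#' @param grm A `grm`.
#' @param prefix Output path prefix.
#' @param ids Animal ids (defaults to 1..n).
#' @return Invisibly, the paths written.
#' @export
write_grm <- function(grm, prefix, ids = NULL) {
  n <- nrow(grm$matrix)
  ids <- ids %||% as.character(seq_len(n))
  i <- rep(seq_len(n), seq_len(n))
  j <- unlist(lapply(seq_len(n), seq_len))
  vals <- grm$matrix[cbind(i, j)]
  lines <- sprintf("%d\t%d\t%d\t%.10g", i, j, length(grm$snp_ids), vals)
  writeLines(lines, paste0(prefix, ".grm"))
  writeLines(ids, paste0(prefix, ".grm.id"))
  invisible(paste0(prefix, c(".grm", ".grm.id")))
}

#' Read a GCTA-style plain-text GRM
#'
#' @param prefix Path prefix used by [write_grm()].
#' @param kind Builder kind to record on the restored object.
#' @return A `grm` (SNP ids are not stored in the format; a count is kept).
#' @export
read_grm <- function(prefix, kind = "vanraden") {
  tab <- utils::read.table(paste0(prefix, ".grm"))
  ids <- readLines(paste0(prefix, ".grm.id"))
  n <- max(tab[[1]])
  G <- matrix(0, n, n)
  G[cbind(tab[[1]], tab[[2]])] <- tab[[4]]
  G[cbind(tab[[2]], tab[[1]])] <- tab[[4]]
  g <- new_grm(G, kind, snp_ids = sprintf("snp%d", seq_len(tab[[3]][1])))
  attr(g, "animal_ids") <- ids
  g
}
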