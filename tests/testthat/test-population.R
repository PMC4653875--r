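# Synthetic population: frequency spectrum, LD structure, family structure,
# marker panels, error injection, QC and PLINK round trips.

test_that("U-shape frequency sampler follows the truncated 1/(p(1-p)) density", {
  n <- 1e5
  p <- sample_ushape_frequencies(n, 0.01, 0.5, seed = 101)
  expect_true(all(p >= 0.01 & p <= 0.5))

  # closed-form CDF via logit differences
  cdf <- function(x) (qlogis(x) - qlogis(0.01)) / (qlogis(0.5) - qlogis(0.01))
  expect_equal(mean(p <= 0.05), cdf(0.05), tolerance = 0.02)

  # chi-square GOF over 20 equal-probability bins
  qs <- sapply(seq(0, 1, length.out = 21), function(u) {
    plogis(qlogis(0.01) + u * (qlogis(0.5) - qlogis(0.01)))
  })
  counts <- table(cut(p, qs, include.lowest = TRUE))
  gof <- chisq.test(as.numeric(counts), p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.01)

  # degenerate interval and determinism contract
  expect_equal(sample_ushape_frequencies(1, 0.25, 0.25 + 1e-12, seed = 1), 0.25,
               tolerance = 1e-9)
  expect_identical(sample_ushape_frequencies(50, seed = 7),
                   sample_ushape_frequencies(50, seed = 7))
  expect_error(sample_ushape_frequencies(10, 0.2, 0.1), "bounds")
  expect_error(sample_ushape_frequencies(10, 0, 0.5), "bounds")
})

test_that("simulated genotypes hit target frequencies and the LD decay law", {
  map <- snp_map(300, n_chrom = 3, spacing_bp = 5000, seed = 21)
  pan <- simulate_genotypes(map, 1000, family = NULL, ld_decay = 5e4, seed = 22)
  p <- allele_frequencies(pan)

  # realized vs target frequency: binomial sampling oracle at 2n gametes
  se <- sqrt(map$target_freq * (1 - map$target_freq) / (2 * 1000))
  expect_lt(mean(abs(p - map$target_freq)), 3 * mean(se))

  # independence limit: ld_decay -> 0 gives adjacent r2 at the 1/n noise floor
  pan0 <- simulate_genotypes(map, 400, family = NULL, ld_decay = 0, seed = 23)
  r2_adj <- function(pan) {
    same <- which(diff(pan$map$chrom) == 0)
    sapply(same, function(j) dosage_r2(pan$dosages[, j], pan$dosages[, j + 1]))
  }
  expect_lt(mean(r2_adj(pan0)), 3 / 400)

  # strong-LD limit: two adjacent equal-frequency SNPs, 50 simulated panels
  map2 <- data.frame(snp_id = c("a", "b"), chrom = 1L, pos = c(100L, 200L),
                     target_freq = 0.3)
  r2s <- sapply(1:50, function(s) {
    pp <- simulate_genotypes(map2, 150, family = NULL, ld_decay = 1e7, seed = 600 + s)
    tryCatch(dosage_r2(pp$dosages[, 1], pp$dosages[, 2]), error = function(e) NA)
  })
  expect_gt(mean(r2s, na.rm = TRUE), 0.8)

  # mean adjacent r2 non-increasing in binned inter-SNP distance
  pan_ld <- simulate_genotypes(snp_map(800, n_chrom = 2, spacing_bp = 8000, seed = 24),
                               600, family = NULL, ld_decay = 3e4, seed = 25)
  same <- which(diff(pan_ld$map$chrom) == 0)
  gaps <- diff(pan_ld$map$pos)[same]
  r2 <- sapply(same, function(j) {
    tryCatch(dosage_r2(pan_ld$dosages[, j], pan_ld$dosages[, j + 1]),
             error = function(e) NA)
  })
  bins <- cut(gaps, quantile(gaps, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE)
  mr2 <- tapply(r2, bins, mean, na.rm = TRUE)
  expect_true(all(diff(mr2) < 0.02))  # non-increasing up to MC jitter

  # determinism and input validation
  expect_identical(simulate_genotypes(map2, 20, seed = 9)$dosages,
                   simulate_genotypes(map2, 20, seed = 9)$dosages)
  bad_map <- map2[2:1, ]
  expect_error(simulate_genotypes(bad_map, 10, seed = 1), "sorted")
})

test_that("half-sib family structure matches the progeny law", {
  map <- snp_map(50, n_chrom = 2, spacing_bp = 5000, seed = 31)
  pan <- simulate_genotypes(map, 1200, family = family_spec(), seed = 32)
  counts <- table(pan$sire_of)
  expect_true(all(!is.na(pan$sire_of)))
  expect_lte(max(counts), 24)
  expect_lt(abs(mean(counts) - 3.1), 0.3)
  pan_u <- simulate_genotypes(map, 50, family = NULL, seed = 33)
  expect_true(all(is.na(pan_u$sire_of)))
})

test_that("marker panel assignment nests sparse panels and biases toward high MAF", {
  pan <- build_study_panel(n_animals = 200, n_snps = 800, n_sparse50 = 240,
                           n_sparse7 = 60, seed = 41)
  expect_length(pan$panels$sparse50, 240)
  expect_length(pan$panels$sparse7, 60)
  expect_true(all(pan$panels$sparse7 %in% pan$panels$sparse50))
  expect_length(candidate_qtl_ids(pan), 800 - 240)
  expect_length(intersect(candidate_qtl_ids(pan), pan$panels$sparse50), 0)

  p <- allele_frequencies(pan)
  maf <- pmin(p, 1 - p)
  names(maf) <- pan$map$snp_id
  expect_gt(mean(maf[pan$panels$sparse50]), mean(maf))
  expect_gt(mean(maf[pan$panels$sparse7]), mean(maf))

  # bias = 0 samples uniformly: sparse MAF histogram matches dense
  pan0 <- assign_marker_panels(pan, 60, 240, high_maf_bias = 0, seed = 5)
  br <- c(0, 0.05, 0.1, 0.2, 0.3, 0.5)
  dense_prop <- as.numeric(table(cut(maf, br, include.lowest = TRUE)))
  sparse_cnt <- as.numeric(table(cut(maf[pan0$panels$sparse50], br,
                                     include.lowest = TRUE)))
  gof <- suppressWarnings(chisq.test(sparse_cnt, p = dense_prop / sum(dense_prop)))
  expect_gt(gof$p.value, 0.01)

  expect_error(assign_marker_panels(pan, 300, 240), "n_sparse7")
  expect_error(assign_marker_panels(pan, 10, 900), "n_sparse7")
})

test_that("genotype error injection is calibrated to the target correlation", {
  X <- rand_dosages(300, 1200, p = runif(1200, 0.05, 0.5), seed = 51)
  pan <- panel_from_matrix(X)
  same <- inject_genotype_errors(pan, 1.0)
  expect_identical(same$dosages, pan$dosages)

  for (target in c(0.98, 0.93)) {
    pert <- inject_genotype_errors(pan, target, seed = 52)
    r <- sapply(seq_len(ncol(X)), function(j) {
      suppressWarnings(cor(pan$dosages[, j], pert$dosages[, j]))
    })
    expect_equal(mean(r, na.rm = TRUE), target, tolerance = 0.01)
    expect_true(all(pert$dosages %in% 0:2))
  }
  expect_error(inject_genotype_errors(pan, 0), "target_correlation")
})

test_that("QC removes SNPs by first failing rule and is idempotent", {
  set.seed(61)
  n <- 100
  clean <- rand_dosages(n, 5, p = 0.3, seed = 62)
  low_maf <- c(rep(1L, 1), rep(0L, n - 1))          # MAF 0.005
  low_call <- rbinom(n, 2, 0.4); low_call[1:6] <- NA # 94% call rate
  hwe_bad <- c(rep(0L, 50), rep(2L, 50))             # (50, 0, 50): X2 = 100
  X <- cbind(clean, low_maf, low_call, hwe_bad)
  pan <- panel_from_matrix(X)
  res <- qc_filter(pan)
  rep_ <- res$report$snps
  expect_setequal(rep_$snp_id, c("s0006", "s0007", "s0008"))
  expect_identical(rep_$reason[rep_$snp_id == "s0006"], "maf")
  expect_identical(rep_$reason[rep_$snp_id == "s0007"], "call_rate")
  expect_identical(rep_$reason[rep_$snp_id == "s0008"], "hwe")
  expect_identical(colnames(res$panel$dosages), sprintf("s%04d", 1:5))

  # the (50,0,50) genotype-count case has 1-df chi-square statistic 100
  p_hat <- 0.5
  e <- n * c(0.25, 0.5, 0.25)
  x2 <- sum((c(50, 0, 50) - e)^2 / e)
  expect_equal(x2, 100)
  expect_lt(pchisq(x2, 1, lower.tail = FALSE), 1e-20)

  # idempotence
  res2 <- qc_filter(res$panel)
  expect_identical(nrow(res2$report$snps), 0L)
  expect_identical(res2$panel$dosages, res$panel$dosages)
})

test_that("close-relative exclusion is greedy on violation counts", {
  X <- rand_dosages(4, 30, seed = 71)
  pan <- panel_from_matrix(X)
  base <- diag(4) * 1.0

  # single offending pair: exactly one of the two removed
  G <- base; G[1, 2] <- G[2, 1] <- 0.5
  res <- exclude_close_relatives(pan, qtlmaf:::new_grm(G, "vanraden", "x"), 0.4)
  expect_identical(res$report$animals$animal_id, "id1")
  expect_equal(res$report$animals$max_kinship, 0.5)
  expect_length(animal_ids(res$panel), 3)

  # all below cutoff: unchanged
  G2 <- base; G2[1, 2] <- G2[2, 1] <- 0.39; G2[3, 4] <- G2[4, 3] <- -0.39
  res2 <- exclude_close_relatives(pan, qtlmaf:::new_grm(G2, "vanraden", "x"), 0.4)
  expect_identical(res2$panel$dosages, pan$dosages)

  # triangle of three mutually related animals: exactly two removed, which is
  # also the minimal removal (any single removal leaves a violating pair)
  G3 <- base
  for (i in 1:3) for (j in 1:3) if (i != j) G3[i, j] <- 0.6
  res3 <- exclude_close_relatives(pan, qtlmaf:::new_grm(G3, "vanraden", "x"), 0.4)
  expect_identical(res3$report$animals$animal_id, c("id1", "id2"))
  for (keep in combn(1:3, 2, simplify = FALSE)) {
    expect_true(abs(G3[keep[1], keep[2]]) > 0.4)  # exhaustive 3x3 check
  }
  # negative relationships count via absolute value
  G4 <- base; G4[1, 2] <- G4[2, 1] <- -0.5
  res4 <- exclude_close_relatives(pan, qtlmaf:::new_grm(G4, "vanraden", "x"), 0.4)
  expect_length(animal_ids(res4$panel), 3)
  expect_error(exclude_close_relatives(pan, qtlmaf:::new_grm(base, "v", "x"), 0),
               "cutoff")
})

test_that("PLINK PED/MAP text files round trip", {
  X <- rand_dosages(12, 25, seed = 81)
  X[2, 3] <- NA
  pan <- panel_from_matrix(X, panels = list(sparse7 = "s0001",
                                            sparse50 = c("s0001", "s0005")))
  prefix <- file.path(withr::local_tempdir(), "pp")
  write_plink(pan, prefix)
  back <- read_plink(prefix)
  expect_identical(unname(back$dosages), unname(pan$dosages))
  expect_identical(animal_ids(back), animal_ids(pan))
  expect_identical(back$map$pos, pan$map$pos)
  expect_identical(back$panels, pan$panels)
})

test_that("PED decoding matches hand decoding and flags malformed lines", {
  dir <- withr::local_tempdir()
  writeLines(c("1\trs1\t0\t500", "1\trs2\t0\t900"),
             file.path(dir, "hand.map"))
  # animal a1: A A (0 copies of C), C C (2 copies); a2: A C, 0 0 (missing)
  writeLines(c("f1 a1 0 0 0 -9 A A C C",
               "f2 a2 0 0 0 -9 A C 0 0"),
             file.path(dir, "hand.ped"))
  pan <- read_plink(file.path(dir, "hand"))
  expect_identical(unname(pan$dosages),
                   matrix(c(0L, 1L, 2L, NA), 2, 2))
  expect_identical(animal_ids(pan), c("a1", "a2"))

  writeLines(c("f1 a1 0 0 0 -9 A A C"), file.path(dir, "bad.ped"))
  writeLines("1\trs1\t0\t500", file.path(dir, "bad.map"))
  expect_error(read_plink(file.path(dir, "bad")), "line 1")
})
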