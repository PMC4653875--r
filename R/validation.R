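# Reference-test validation design: replicated random splits, trait
# regeneration, GREML fitting on the reference set, GEBV prediction for the
# masked test set, and summaries (mean/SD over replicates) of estimated
# heritability and TBV-GEBV accuracy.

#' Scenario configuration
#'
#' Validated bundle of the factors a scenario varies: QTL MAF category,
#' heritability setting, number of QTLs, effect model, marker density, the
#' prediction model, and the reference-test split rule. Categorical factors
#' are restricted to the supported grids; split sizes adapt to the simulated
#' population.
#'
#' @param maf_category `"all"`, `"high"` or `"low"`.
#' @param h2_true One of 0.2, 0.4, 0.8.
#' @param n_qtl One of 50, 100, 300, 500, 1000, 2000.
#' @param effect_model `"equal_variance"` or `"gamma"`.
#' @param panel Marker density: `"sparse7"`, `"sparse50"`, `"sparse7_err"`,
#'   `"sparse50_err"` or `"dense"`. The `_err` densities use the dense SNP
#'   set with dosage errors calibrated to true-vs-recovered correlations of
#'   0.93 and 0.98 respectively.
#' @param model Prediction model: `"m1_V"`, `"m1_Y"`, `"m1_S"` (single
#'   component with the VanRaden / Yang / LD-weighted GRM) or `"m2"`
#'   (two-component with the MAF-partitioned Yang pair).
#' @param split_mode `"test_fraction"` or `"reference_size"`.
#' @param split_value Fraction in (0,1) or reference count, per `split_mode`.
#' @param n_replicates Replicates of the reference-test design (default 300).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(maf_category = "all", h2_true = 0.4, n_qtl = 500,
                            effect_model = "equal_variance", panel = "sparse50",
                            model = "m1_Y", split_mode = "test_fraction",
                            split_value = 0.1, n_replicates = 300L) {
  maf_category <- match.arg(maf_category, c("all", "high", "low"))
  if (!h2_true %in% c(0.2, 0.4, 0.8)) {
    stop("`h2_true` must be one of 0.2, 0.4, 0.8", call. = FALSE)
  }
  if (!n_qtl %in% c(50, 100, 300, 500, 1000, 2000)) {
    stop("`n_qtl` must be one of 50, 100, 300, 500, 1000, 2000", call. = FALSE)
  }
  effect_model <- match.arg(effect_model, c("equal_variance", "gamma"))
  panel <- match.arg(panel, c("sparse7", "sparse50", "sparse7_err",
                              "sparse50_err", "dense"))
  model <- match.arg(model, c("m1_V", "m1_Y", "m1_S", "m2"))
  split_mode <- match.arg(split_mode, c("test_fraction", "reference_size"))
  stopifnot(n_replicates >= 1)
  structure(list(
    maf_category = maf_category, h2_true = h2_true, n_qtl = n_qtl,
    effect_model = effect_model, panel = panel, model = model,
    split_mode = split_mode, split_value = split_value,
    n_replicates = as.integer(n_replicates)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "scenario_config: %s MAF, h2 = %.1f, %d QTLs (%s), panel %s, model %s, %s = %s, %d replicates\n",
    x$maf_category, x$h2_true, x$n_qtl, x$effect_model, x$panel, x$model,
    x$split_mode, format(x$split_value), x$n_replicates))
  invisible(x)
}

# dosage-error correlations the error-injected densities are calibrated to
err_panel_correlation <- c(sparse7_err = 0.93, sparse50_err = 0.98)

#' Random reference-test split
#'
#' `test_fraction` mode puts `round_half_up(fraction * n)` animals in the
#' test set; `reference_size` mode samples exactly that many reference
#' animals. A one-tenth split of 1368 animals yields 137 test and 1231
#' reference animals.
#'
#' @param animal_ids Character vector of ids.
#' @param mode `"test_fraction"` or `"reference_size"`.
#' @param value Fraction in (0, 1) or reference count in (0, n).
#' @param seed Optional integer seed.
#' @return Object of class `split_plan` with `reference_ids`, `test_ids`.
#' @export
split_reference_test <- function(animal_ids, mode = c("test_fraction", "reference_size"),
                                 value, seed = NULL) {
  mode <- match.arg(mode)
  n <- length(animal_ids)
  n_test <- if (mode == "test_fraction") {
    if (!(value > 0 && value < 1)) stop("fraction must lie in (0, 1)", call. = FALSE)
    round_half_up(value * n)
  } else {
    if (!(value > 0 && value < n)) stop("reference size out of range", call. = FALSE)
    n - value
  }
  if (!(n_test > 0 && n_test < n)) {
    stop("split leaves an empty reference or test set", call. = FALSE)
  }
  with_seed(seed, {
    test <- sample(animal_ids, n_test)
    structure(list(reference_ids = setdiff(animal_ids, test),
                   test_ids = sort(test)),
              class = "split_plan")
  })
}

#' Prediction accuracy: Pearson correlation of TBV and GEBV
#'
#' @param tbv,gebv Numeric vectors of equal length (>= 3), both non-constant.
#' @return Sample Pearson correlation.
#' @export
accuracy <- function(tbv, gebv) {
  if (length(tbv) != length(gebv) || length(tbv) < 3) {
    stop("need two equal-length vectors of at least 3 animals", call. = FALSE)
  }
  if (stats::sd(tbv) == 0 || stats::sd(gebv) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(tbv, gebv)
}

#' Expected GBLUP accuracy (deterministic formula)
#'
#' `r = sqrt(N h^2 / (N h^2 + q))` with `N` reference animals, heritability
#' `h^2` and `q` independent loci: the classical expectation that accuracy
#' grows with reference size and heritability but not with the number of
#' QTLs.
#'
#' @param N Reference population size (>= 0).
#' @param h2 Heritability in (0, 1].
#' @param q Number of independent loci (> 0).
#' @return Expected accuracy in `[0, 1)`.
#' @export
expected_accuracy <- function(N, h2, q) {
  if (!(q > 0)) stop("`q` must be positive", call. = FALSE)
  if (!(N >= 0)) stop("`N` must be non-negative", call. = FALSE)
  if (!(h2 > 0 && h2 <= 1)) stop("`h2` must lie in (0, 1]", call. = FALSE)
  sqrt(N * h2 / (N * h2 + q))
}

#' Build the GRM(s) a scenario's prediction model needs
#'
#' Resolves the marker density (injecting calibrated dosage errors for the
#' `_err` densities), drops monomorphic markers, builds the GRM(s) for the
#' configured model, and regularises each with the standard 1e-5 diagonal
#' jitter. The result depends only on the panel and config, so drivers
#' compute it once and share it across replicates.
#'
#' @param panel A QC'd `genotype_panel`.
#' @param config A `scenario_config`.
#' @param seed Optional seed (used by error injection only).
#' @return List of one or two regularised `grm`s (order low, high for `m2`).
#' @export
scenario_grms <- function(panel, config, seed = NULL) {
  gp <- panel
  if (config$panel %in% names(err_panel_correlation)) {
    gp <- inject_genotype_errors(panel, err_panel_correlation[[config$panel]],
                                 seed = seed)
  }
  ids <- marker_ids(gp, config$panel)
  p <- allele_frequencies(gp, ids)
  ids <- ids[p > 0 & p < 1]
  grms <- switch(config$model,
    m1_V = list(build_grm_vanraden(gp, ids)),
    m1_Y = list(build_grm_yang(gp, ids)),
    m1_S = {
      w <- compute_ld_weights(gp, ids,
                              passes = if (config$panel == "sparse7") 1L else 2L)
      list(build_grm_speed(gp, ids, w))
    },
    m2 = unname(partition_grms_by_maf(gp, ids))
  )
  lapply(grms, regularize_grm)
}

#' Run one replicate of the reference-test design
#'
#' Executes the full generative and evaluation pipeline for one replicate:
#' sample QTLs, draw and standardise effects, simulate phenotypes, split,
#' fit the configured GREML model on the reference animals, predict GEBV for
#' the masked test animals, and score the TBV-GEBV correlation. Fully
#' determined by `seed`.
#'
#' @param panel A QC'd `genotype_panel`.
#' @param config A `scenario_config`.
#' @param seed Optional integer replicate seed.
#' @param grms Optional precomputed [scenario_grms()] output; computed on the
#'   fly when `NULL`.
#' @return Object of class `replicate_result`: `h2_est`, `accuracy`, `aic`,
#'   `loglik`, `converged`, `boundary`, `n_reference`, `n_test`.
#' @export
run_replicate <- function(panel, config, seed = NULL, grms = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, {
    step <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
      })
    }
    qtls <- step("sample_qtls",
                 sample_qtls(panel, config$maf_category, config$n_qtl))
    qtls <- step("draw_effects", draw_effects(qtls, config$effect_model))
    qtls <- step("standardize_effects",
                 standardize_effects(qtls, panel, config$h2_true))
    tbv <- step("compute_tbv", compute_tbv(panel, qtls))
    trait <- step("simulate_phenotypes", simulate_phenotypes(tbv, config$h2_true))
    split <- step("split", split_reference_test(animal_ids(panel),
                                                config$split_mode,
                                                config$split_value))
    if (is.null(grms)) grms <- step("build_grm", scenario_grms(panel, config))
    ids <- animal_ids(panel)
    ref <- match(split$reference_ids, ids)
    test <- match(split$test_ids, ids)
    fit <- step("reml_fit", suppressWarnings(
      reml_fit(trait$y[ref], lapply(grms, subset_grm, idx = ref))))
    pred <- step("predict_gebv",
                 predict_gebv(fit, trait$y[ref], grms, ref, test, ids = ids))
    acc <- step("accuracy", accuracy(tbv[test], pred$gebv))
    structure(list(
      h2_est = fit$h2, accuracy = acc, aic = fit$aic, loglik = fit$loglik,
      converged = fit$converged, boundary = fit$boundary,
      n_reference = length(ref), n_test = length(test)
    ), class = "replicate_result")
  })
}

# documented counter scheme: replicate i runs under seed
# (master + 7919 * i) mod (2^31 - 1), so any replicate reruns in isolation
replicate_seeds <- function(master_seed, n) {
  (as.numeric(master_seed) + 7919 * seq_len(n)) %% 2147483647
}

#' Run a replicated validation scenario
#'
#' Derives one seed per replicate from the master seed (so any replicate can
#' be rerun in isolation), shares the scenario GRM(s) across replicates, and
#' summarises estimated heritability and accuracy as mean and SD (denominator
#' n-1) over replicates — overall and over converged replicates only.
#' Replicate failures are recorded and tolerated up to 20%.
#'
#' @param panel A QC'd `genotype_panel`.
#' @param config A `scenario_config`.
#' @param seed Master integer seed.
#' @param n_replicates Overrides `config$n_replicates` when given.
#' @return Object of class `validation_summary`: per-replicate `results`
#'   data.frame, `summary` data.frame, the config, seeds and failure log.
#' @export
run_scenario <- function(panel, config, seed = 1L, n_replicates = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  nrep <- as.integer(n_replicates %||% config$n_replicates)
  if (nrep < 2) stop("need at least 2 replicates", call. = FALSE)
  grms <- scenario_grms(panel, config, seed = seed)
  seeds <- replicate_seeds(seed, nrep)
  rows <- vector("list", nrep)
  failures <- character()
  for (i in seq_len(nrep)) {
    res <- tryCatch(run_replicate(panel, config, seed = seeds[i], grms = grms),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("replicate %d: %s", i, res))
      next
    }
    rows[[i]] <- data.frame(replicate = i, seed = seeds[i],
                            h2_est = res$h2_est, accuracy = res$accuracy,
                            aic = res$aic, converged = res$converged,
                            boundary = res$boundary)
  }
  if (length(failures) > 0.2 * nrep) {
    stop("more than 20% of replicates failed; first failure: ", failures[1],
         call. = FALSE)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  summarise <- function(df, label) {
    data.frame(subset = label, n = nrow(df),
               h2_mean = mean(df$h2_est), h2_sd = stats::sd(df$h2_est),
               accuracy_mean = mean(df$accuracy),
               accuracy_sd = stats::sd(df$accuracy),
               aic_mean = mean(df$aic))
  }
  summ <- rbind(summarise(results, "all"),
                summarise(results[results$converged, , drop = FALSE], "converged"))
  structure(list(results = results, summary = summ, config = config,
                 master_seed = seed, replicate_seeds = seeds,
                 failures = failures),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("validation_summary: %d replicates (%d failed)\n",
              x$config$n_replicates, length(x$failures)))
  print(x$config)
  print(x$summary, row.names = FALSE)
  invisible(x)
}
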