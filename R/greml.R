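# Restricted maximum likelihood for the one- and two-component GBLUP models
#   y = 1 mu + u + e,            u   ~ N(0, G sigma_u^2)
#   y = 1 mu + u_L + u_H + e,    u_c ~ N(0, G_c sigma_c^2)
# fitted by average-information (AI) REML with EM fallback steps, components
# constrained non-negative, and GEBV prediction for masked test animals via
# the BLUP conditional expectation.

# Restricted log-likelihood pieces at a given set of variance components.
# Ks includes the identity last (residual). Returns NULL if V is not PD.
reml_pieces <- function(y, Ks, sigma) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (c in seq_along(Ks)) V <- V + sigma[c] * Ks[[c]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  Vi1 <- rowSums(Vi)             # Vi %*% ones
  xvx <- sum(Vi1)                # 1' Vi 1
  Viy <- drop(Vi %*% y)
  mu <- sum(Vi1 * y) / xvx
  Py <- Viy - Vi1 * mu           # P y with X = 1
  yPy <- sum(y * Py)
  # full error-contrast likelihood incl. the log|X'X| = log(n) normalisation,
  # so values are comparable across models and match closed forms exactly
  ll <- -0.5 * (logdetV + log(xvx) - log(n) + yPy + (n - 1) * log(2 * pi))
  list(loglik = ll, Vi = Vi, Vi1 = Vi1, xvx = xvx, Py = Py, mu = mu)
}

#' Restricted log-likelihood at given variance components
#'
#' Exact restricted log-likelihood (intercept-only fixed effects, all
#' constants included) of the mixed model at the supplied components. Serves
#' as an independent check surface for [reml_fit()]: the fitted optimum must
#' dominate any grid of candidate components.
#'
#' @param y Phenotype vector.
#' @param grms A `grm` or list of one or two `grm`s (genetic components).
#' @param components Variance components in trait units: one value per GRM
#'   followed by the residual variance. All `>= 0`, not all zero.
#' @return The restricted log-likelihood (scalar).
#' @export
profile_loglik <- function(y, grms, components) {
  if (inherits(grms, "grm")) grms <- list(grms)
  n <- length(y)
  Ks <- c(lapply(grms, function(g) g$matrix), list(diag(n)))
  if (length(components) != length(Ks)) {
    stop("`components` must have one entry per GRM plus the residual",
         call. = FALSE)
  }
  if (any(components < 0) || all(components == 0)) {
    stop("components must be >= 0 and not all zero", call. = FALSE)
  }
  pc <- reml_pieces(y, Ks, components)
  if (is.null(pc)) stop("total covariance is singular at these components",
                        call. = FALSE)
  pc$loglik
}

#' Fit a GREML model by average-information REML
#'
#' Maximises the restricted likelihood of an intercept-plus-polygenic model
#' with one (`single`) or two (`two_component`) genomic variance components.
#' Each iteration proposes an AI (expected-information) step with step
#' halving so the restricted log-likelihood never decreases; when the AI
#' system is ill-conditioned or the step fails, an EM step is used instead.
#' Components are clamped at a floor of `1e-8 * var(y)` (boundary estimates
#' are reported with `boundary = TRUE`). Heritability is
#' `h1^2 = sigma_u^2 / (sigma_u^2 + sigma_e^2)` for the single model and
#' `h2^2 = (sigma_uL^2 + sigma_uH^2) / (sigma_uL^2 + sigma_uH^2 + sigma_e^2)`
#' for the two-component model.
#'
#' @param y Phenotypes of the reference animals (length >= 30, variance > 0).
#' @param grms A `grm` or list of one or two (regularised) `grm`s restricted
#'   to the reference animals.
#' @param max_iter Maximum REML iterations.
#' @param tol_loglik Convergence threshold on the log-likelihood change.
#' @param tol_par Convergence threshold on the largest component change.
#' @return Object of class `reml_fit` with fields `model`, `sigma` (named
#'   variance components, residual last), `mu`, `loglik`, `loglik_trace`,
#'   `v` (number of variance components), `aic`, `h2`, `converged`,
#'   `boundary`, `degenerate`, `n_iter`, `grm_kinds`, `n`.
#' @export
reml_fit <- function(y, grms, max_iter = 100L, tol_loglik = 1e-6,
                     tol_par = 1e-8) {
  if (inherits(grms, "grm")) grms <- list(grms)
  n <- length(y)
  if (n < 30) stop("need at least 30 reference animals", call. = FALSE)
  if (stats::var(y) <= 0) stop("phenotype variance is zero", call. = FALSE)
  ngen <- length(grms)
  if (!ngen %in% c(1L, 2L)) stop("supply one or two GRMs", call. = FALSE)
  for (g in grms) {
    if (!inherits(g, "grm")) stop("`grms` must contain grm objects", call. = FALSE)
    if (nrow(g$matrix) != n) stop("GRM dimension does not match length(y)",
                                  call. = FALSE)
  }
  model <- if (ngen == 1L) "single" else "two_component"
  Ks <- c(lapply(grms, function(g) g$matrix), list(diag(n)))
  nv <- ngen + 1L
  vy <- stats::var(y)
  floorv <- 1e-8 * vy
  sigma <- rep(vy / nv, nv)

  pc <- reml_pieces(y, Ks, sigma)
  if (is.null(pc)) stop("initial covariance singular", call. = FALSE)
  trace <- pc$loglik
  converged <- FALSE
  degenerate <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # first derivatives and AI matrix
    trPK <- yPKPy <- numeric(nv)
    u <- vector("list", nv)
    for (c in seq_len(nv)) {
      Kc <- Ks[[c]]
      uc <- if (c == nv) pc$Py else drop(Kc %*% pc$Py)
      u[[c]] <- uc
      yPKPy[c] <- sum(pc$Py * uc)
      if (c == nv) {
        trPK[c] <- sum(diag(pc$Vi)) - sum(pc$Vi1^2) / pc$xvx
      } else {
        KV1 <- drop(Kc %*% pc$Vi1)
        trPK[c] <- sum(pc$Vi * Kc) - sum(pc$Vi1 * KV1) / pc$xvx
      }
    }
    score <- -0.5 * (trPK - yPKPy)
    AI <- matrix(0, nv, nv)
    Pu <- lapply(u, function(uc) {
      drop(pc$Vi %*% uc) - pc$Vi1 * (sum(pc$Vi1 * uc) / pc$xvx)
    })
    for (c in seq_len(nv)) {
      for (d in c:nv) {
        AI[c, d] <- AI[d, c] <- 0.5 * sum(u[[c]] * Pu[[d]])
      }
    }
    if (rcond(AI) < 1e-12) degenerate <- TRUE

    accepted <- FALSE
    delta <- tryCatch(
      solve(AI + diag(1e-8 * max(diag(AI)), nv), score),
      error = function(e) NULL
    )
    if (!is.null(delta) && all(is.finite(delta))) {
      h <- 1
      for (k in 1:8) {
        cand <- pmax(sigma + h * delta, floorv)
        pc2 <- reml_pieces(y, Ks, cand)
        if (!is.null(pc2) && pc2$loglik >= pc$loglik - 1e-10) {
          accepted <- TRUE
          break
        }
        h <- h / 2
      }
    }
    if (!accepted) {
      cand <- pmax(sigma + sigma^2 * (yPKPy - trPK) / n, floorv)
      pc2 <- reml_pieces(y, Ks, cand)
      if (is.null(pc2) || pc2$loglik < pc$loglik - 1e-8) {
        break  # no admissible ascent step; stop at current point
      }
      accepted <- TRUE
    }
    dll <- pc2$loglik - pc$loglik
    dpar <- max(abs(cand - sigma))
    sigma <- cand
    pc <- pc2
    trace <- c(trace, pc$loglik)
    if (abs(dll) < tol_loglik || dpar < tol_par) {
      converged <- TRUE
      break
    }
  }
  if (degenerate) {
    warning("variance components poorly identified (near-singular AI matrix); ",
            "estimates lie on a likelihood ridge", call. = FALSE)
  }

  names(sigma) <- if (model == "single") c("u", "e") else c("u_low", "u_high", "e")
  gen <- sum(sigma[-nv])
  h2 <- gen / (gen + sigma[[nv]])
  structure(list(
    model = model, sigma = sigma, mu = pc$mu,
    loglik = pc$loglik, loglik_trace = trace,
    v = nv, aic = 2 * nv - 2 * pc$loglik, h2 = unname(h2),
    converged = converged, boundary = any(sigma <= floorv * 1.000001),
    degenerate = degenerate, n_iter = it,
    grm_kinds = vapply(grms, function(g) g$kind, character(1)), n = n
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit (%s, n = %d): %s; h2 = %.3f; logLik = %.3f; AIC = %.1f; %s in %d iter\n",
              x$model, x$n,
              paste(sprintf("%s = %.3f", names(x$sigma), x$sigma), collapse = ", "),
              x$h2, x$loglik, x$aic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$loglik, df = object$v + 1, class = "logLik")
}

#' Akaike information criterion of a REML fit
#'
#' `AIC = k * v - 2 * logLik` with `v` the number of variance components
#' (2 for the single model, 3 for the two-component model) and `k = 2`.
#'
#' @param object A `reml_fit`.
#' @param ... Unused.
#' @param k Penalty per parameter (default 2).
#' @return Numeric scalar.
#' @export
AIC.reml_fit <- function(object, ..., k = 2) {
  k * object$v - 2 * object$loglik
}

#' Predict genomic breeding values for masked animals
#'
#' BLUP conditional expectation using components and mean estimated on the
#' reference animals, with cross-covariance blocks taken from the full-sample
#' GRM(s):
#' `u_hat = sum_c sigma_c^2 G_c[new, ref] V_ref^{-1} (y_ref - 1 mu)`,
#' `V_ref = sum_c sigma_c^2 G_c[ref, ref] + sigma_e^2 I`.
#'
#' @param fit A `reml_fit` estimated on the reference animals.
#' @param y_ref Reference phenotypes (same order as `ref`).
#' @param grms_full A `grm` or list of `grm`s over all animals, same kinds and
#'   order as used in the fit.
#' @param ref,test Indices (or ids matching `ids`) of reference and test
#'   animals; must be disjoint.
#' @param ids Optional animal ids labelling the GRM rows.
#' @return Object of class `gebv_result`: data.frame with `animal_id` and
#'   `gebv`, plus the fit's model and GRM kinds as attributes.
#' @export
predict_gebv <- function(fit, y_ref, grms_full, ref, test, ids = NULL) {
  if (inherits(grms_full, "grm")) grms_full <- list(grms_full)
  nall <- nrow(grms_full[[1]]$matrix)
  ids <- ids %||% as.character(seq_len(nall))
  if (is.character(ref)) ref <- match(ref, ids)
  if (is.character(test)) test <- match(test, ids)
  if (length(intersect(ref, test)) > 0) {
    stop("reference and test sets must be disjoint", call. = FALSE)
  }
  ngen <- length(grms_full)
  if (ngen != fit$v - 1L) stop("GRM count does not match the fit", call. = FALSE)
  if (length(y_ref) != length(ref)) stop("length(y_ref) != length(ref)", call. = FALSE)
  sig <- fit$sigma
  V <- diag(sig[[length(sig)]], length(ref))
  for (c in seq_len(ngen)) {
    V <- V + sig[[c]] * grms_full[[c]]$matrix[ref, ref, drop = FALSE]
  }
  sol <- tryCatch(solve(V, y_ref - fit$mu), error = function(e) {
    stop("reference covariance matrix is singular", call. = FALSE)
  })
  gebv <- rep(0, length(test))
  for (c in seq_len(ngen)) {
    gebv <- gebv + sig[[c]] * drop(grms_full[[c]]$matrix[test, ref, drop = FALSE] %*% sol)
  }
  structure(
    data.frame(animal_id = ids[test], gebv = gebv, stringsAsFactors = FALSE),
    model = fit$model, grm_kinds = fit$grm_kinds,
    class = c("gebv_result", "data.frame")
  )
}

#' Write a REML fit report as TSV
#' @param fit A `reml_fit`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(fit, path) {
  row <- data.frame(model = fit$model, t(fit$sigma), mu = fit$mu,
                    loglik = fit$loglik, v = fit$v, aic = fit$aic, h2 = fit$h2,
                    converged = fit$converged, n_iter = fit$n_iter)
  utils::write.table(row, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write GEBV predictions as TSV (animal_id, gebv)
#' @param gebv A `gebv_result`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gebv <- function(gebv, path) {
  utils::write.table(as.data.frame(gebv), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
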