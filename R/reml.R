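# Average-information REML for multi-component animal models.
#
# The phenotypic covariance is V = sum_k Z G_k Z' s2_k + I s2_e. Updates use
# the average-information matrix AI_kl = y'P V_k P V_l P y / 2 with the
# REML gradient g_k = -(tr(P V_k) - y'P V_k P y) / 2, where
# P = Vinv - Vinv X (X'Vinv X)^-1 X'Vinv. Any AI step that would push a
# component below the boundary constant (or that fails to improve the
# likelihood after step halving) is replaced by the slower but monotone
# expectation-maximisation update. Traces use tr(AB) = sum(A * B) for
# symmetric B, keeping each iteration at O(n^3) for the single V inverse.

# Evaluate the restricted log-likelihood and the quantities reused by one
# AI/EM update at the given variances.
reml_eval <- function(ds, theta, structures) {
  N <- ds$n_records
  V <- diag(theta[length(theta)], N)
  for (k in seq_along(structures)) V <- V + theta[k] * structures[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    abort(sprintf("V is numerically singular (reciprocal condition ~ %.2e).",
                  rcond(V)))
  }
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  X <- ds$X
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  chx <- chol(XtVinvX)
  logdetX <- 2 * sum(log(diag(chx)))
  XtVinvX_inv <- chol2inv(chx)
  beta <- XtVinvX_inv %*% crossprod(VinvX, ds$y)
  P <- Vinv - VinvX %*% tcrossprod(XtVinvX_inv, VinvX)
  Py <- P %*% ds$y
  yPy <- drop(crossprod(ds$y, Py))
  list(loglik = -0.5 * (logdetV + logdetX + yPy),
       P = P, Py = Py, beta = beta, XtVinvX_inv = XtVinvX_inv)
}

reml_structures <- function(ds) {
  lapply(ds$G, function(G) ds$Z %*% tcrossprod(G, ds$Z))
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates -1/2 (log|V| + log|X'V^-1 X| + y'Py) for the model defined by a
#' design system, with V = sum_k Z G_k Z' s2_k + I s2_e. Constant terms are
#' omitted, so values are comparable across models sharing the same fixed
#' structure and data.
#'
#' @param ds A design system from [build_design()].
#' @param variances Named numeric vector: one value per random term of the
#'   spec plus `residual`.
#' @return The restricted log-likelihood (a scalar).
#' @export
reml_loglikelihood <- function(ds, variances) {
  stopifnot(inherits(ds, "design_system"))
  theta <- variance_vector(ds, variances)
  reml_eval(ds, theta, reml_structures(ds))$loglik
}

variance_vector <- function(ds, variances) {
  labels <- c(names(ds$G), "residual")
  if (is.null(names(variances))) {
    if (length(variances) != length(labels)) {
      abort(sprintf("expected %d variances (%s).", length(labels),
                    paste(labels, collapse = ", ")))
    }
    return(as.numeric(variances))
  }
  if (!all(labels %in% names(variances))) {
    abort(sprintf("`variances` must name: %s", paste(labels, collapse = ", ")))
  }
  as.numeric(variances[labels])
}

#' Fit a variance-component model by AI-REML
#'
#' Maximises the restricted likelihood over the variance components of the
#' model, starting from an equal split of the phenotypic variance across all
#' components. Updates are average-information steps with step halving; a
#' step that would drive a component below the boundary constant is replaced
#' by an expectation-maximisation step, and components pinned at the
#' boundary are flagged (`at_boundary`). Standard errors come from the
#' inverse average-information matrix at the optimum, and BLUP solutions for
#' every random term (the additive term's vector being the GEBVs) from the
#' mixed-model identities at the final variances.
#'
#' @param ds A design system from [build_design()].
#' @param max_iter Maximum iterations.
#' @param convergence_tol Relative log-likelihood change declaring
#'   convergence (parameters must also be stable to 10x this tolerance).
#' @param boundary_constant Lower bound for every component, as a fraction
#'   of the sample phenotypic variance.
#' @param start Optional named start values (defaults to the equal split).
#' @return A `reml_fit` object; see [tidy.reml_fit()] and
#'   [glance.reml_fit()] for tabular summaries.
#' @export
fit_reml <- function(ds, max_iter = 200L, convergence_tol = 1e-8,
                     boundary_constant = 1e-8, start = NULL) {
  stopifnot(inherits(ds, "design_system"))
  if (ds$n_records <= ncol(ds$X) + 1L) {
    abort("too few records for the fixed structure.")
  }
  structures <- reml_structures(ds)
  k <- length(structures)
  labels <- c(names(ds$G), "residual")
  vp <- var(ds$y)
  bound <- boundary_constant * vp
  theta <- if (is.null(start)) rep(vp / (k + 1), k + 1) else {
    pmax(variance_vector(ds, start), bound)
  }

  ev <- reml_eval(ds, theta, structures)
  converged <- FALSE
  iter <- 0L
  AI <- NULL
  trace <- list()
  while (iter < max_iter) {
    iter <- iter + 1L
    P <- ev$P; Py <- ev$Py
    # gradient and AI matrix over all k+1 components (residual last, V_e = I)
    w <- vector("list", k + 1L)
    grad <- numeric(k + 1L)
    for (j in seq_len(k)) {
      Vj <- structures[[j]]
      grad[j] <- -0.5 * (sum(P * Vj) - drop(crossprod(Py, Vj %*% Py)))
      w[[j]] <- Vj %*% Py
    }
    grad[k + 1L] <- -0.5 * (sum(diag(P)) - drop(crossprod(Py)))
    w[[k + 1L]] <- Py
    AI <- matrix(0, k + 1L, k + 1L)
    Pw <- lapply(w, function(wi) P %*% wi)
    for (a in seq_len(k + 1L)) {
      for (b in a:(k + 1L)) {
        AI[a, b] <- AI[b, a] <- 0.5 * drop(crossprod(w[[a]], Pw[[b]]))
      }
    }

    # Average-information proposal with active-set boundary handling: any
    # component whose update falls below the bound is pinned there and the
    # AI system re-solved over the remaining free components.
    propose_ai <- function() {
      pinned <- theta <= bound & grad < 0
      repeat {
        free <- which(!pinned)
        if (!length(free)) return(pmax(theta, bound))
        delta_free <- tryCatch(solve(AI[free, free, drop = FALSE], grad[free]),
                               error = function(e) NULL)
        if (is.null(delta_free)) return(NULL)
        prop <- ifelse(pinned, bound, theta)
        prop[free] <- theta[free] + delta_free
        viol <- prop < bound
        if (!any(viol & !pinned)) return(pmax(prop, bound))
        pinned <- pinned | viol
      }
    }
    step_ok <- FALSE
    prop <- propose_ai()
    if (!is.null(prop)) {
      for (halve in 0:5) {
        cand <- theta + (prop - theta) / 2^halve
        cand <- pmax(cand, bound)
        ev_cand <- tryCatch(reml_eval(ds, cand, structures),
                            error = function(e) NULL)
        if (!is.null(ev_cand) && ev_cand$loglik >= ev$loglik - 1e-10) {
          step_ok <- TRUE
          break
        }
      }
    }
    if (!step_ok) {
      # EM-REML update (Harville form), monotone and positivity-preserving:
      # s2_new = s2 + s2^2/q * (y'P V_k P y - tr(P V_k))
      q <- c(rep(ds$n_animals, k), ds$n_records)
      cand <- theta + (theta^2 / q) * (2 * grad)
      cand <- pmax(cand, bound)
      ev_cand <- reml_eval(ds, cand, structures)
    }
    rel_ll <- abs(ev_cand$loglik - ev$loglik) / max(1, abs(ev$loglik))
    pinned_now <- cand <= bound
    free_now <- !pinned_now
    rel_par <- if (any(free_now)) {
      max(abs(cand - theta)[free_now] / pmax(theta, bound)[free_now])
    } else 0
    theta <- cand
    ev <- ev_cand
    trace[[iter]] <- c(iter = iter, loglik = ev$loglik, setNames(theta, labels))
    if (rel_ll < convergence_tol && rel_par < 10 * convergence_tol) {
      converged <- TRUE
      break
    }
  }

  at_boundary <- labels[theta <= bound * (1 + 1e-6)]
  se <- rep(NA_real_, k + 1L)
  vcov_theta <- matrix(NA_real_, k + 1L, k + 1L)
  inv_ai <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(inv_ai)) {
    vcov_theta <- inv_ai
    se <- sqrt(pmax(diag(inv_ai), 0))
  }
  dimnames(vcov_theta) <- list(labels, labels)

  # BLUPs at the final variances: u_k = s2_k G_k Z' P y
  ZtPy <- crossprod(ds$Z, ev$Py)
  blup <- list()
  for (j in seq_len(k)) {
    blup[[labels[j]]] <- setNames(drop(theta[j] * ds$G[[j]] %*% ZtPy),
                                  ds$animal_ids)
  }

  fixed <- tibble::tibble(term = colnames(ds$X), estimate = drop(ev$beta),
                          std_error = sqrt(pmax(diag(ev$XtVinvX_inv), 0)))
  loglik <- ev$loglik
  structure(list(
    spec = ds$spec,
    variances = tibble::tibble(term = labels, estimate = theta,
                               std_error = se,
                               at_boundary = labels %in% at_boundary),
    vcov = vcov_theta,
    fixed_solutions = fixed,
    blup = blup,
    reml_loglik = loglik,
    aic = -2 * loglik + 2 * (k + 1L),
    n_params = k + 1L,
    converged = converged,
    n_iterations = iter,
    at_boundary = at_boundary,
    boundary = bound,
    n_records = ds$n_records,
    n_animals = ds$n_animals,
    trace = dplyr::bind_rows(lapply(trace, function(x) tibble::as_tibble(as.list(x))))
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit %s: logL = %.4f, AIC = %.4f, %s in %d iter>\n",
              x$spec$name, x$reml_loglik, x$aic,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(x$variances)
  invisible(x)
}

#' Genomic estimated breeding values of a fit
#'
#' The BLUP solutions of the additive term, the quantity ranked and
#' cross-validated throughout the package.
#'
#' @param fit A `reml_fit`.
#' @return Named numeric vector of per-animal GEBVs.
#' @export
gebv <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (is.null(fit$blup$additive)) abort("fit has no additive term.")
  fit$blup$additive
}

#' Akaike information criterion of a REML fit
#'
#' AIC = -2 logL + 2t with t the number of estimated variance parameters
#' (fixed effects are profiled out of the restricted likelihood and do not
#' count). Comparable only across models sharing the fixed structure.
#'
#' @param fit A `reml_fit`.
#' @return The AIC value.
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  -2 * fit$reml_loglik + 2 * fit$n_params
}

#' Variance ratios (heritabilities) from estimated components
#'
#' With the phenotypic denominator, each genetic ratio is the component over
#' the sum of all estimated variances (including permanent environment and
#' residual) — the narrow-sense heritability for the additive term. With the
#' total-genetic denominator, dominance and additive-by-additive components
#' are expressed relative to sigma^2_g = s2_a + s2_d + s2_aa. Standard
#' errors (available for fitted models) use the delta method on the inverse
#' average-information covariance of the estimates.
#'
#' @param fit A `reml_fit`, or a named numeric vector of variance components
#'   (must include `residual`) for worked examples from printed tables.
#' @param denominator `"phenotypic"` or `"total_genetic"`.
#' @return A tibble with columns `term`, `ratio`, `std_error` (NA when no
#'   covariance is available).
#' @export
#' @examples
#' variance_ratios(c(additive = 1310.62, residual = 2190.12))
variance_ratios <- function(fit, denominator = c("phenotypic", "total_genetic")) {
  denominator <- match.arg(denominator)
  if (inherits(fit, "reml_fit")) {
    est <- setNames(fit$variances$estimate, fit$variances$term)
    vc <- fit$vcov
  } else {
    est <- fit
    if (!"residual" %in% names(est)) abort("components must include `residual`.")
    vc <- NULL
  }
  genetic <- intersect(c("additive", "dominance", "aa", "ad", "dd"), names(est))
  if (denominator == "phenotypic") {
    terms <- genetic
    denom_terms <- names(est)
  } else {
    terms <- intersect(c("dominance", "aa"), names(est))
    denom_terms <- intersect(c("additive", "dominance", "aa"), names(est))
  }
  S <- sum(est[denom_terms])
  if (S <= 0) abort("zero denominator for variance ratios.")
  out <- tibble::tibble(
    term = terms,
    ratio = unname(est[terms]) / S,
    std_error = NA_real_
  )
  if (!is.null(vc) && !anyNA(vc)) {
    for (i in seq_along(terms)) {
      # gradient of s_k / S wrt each component
      g <- setNames(numeric(length(est)), names(est))
      g[denom_terms] <- -est[terms[i]] / S^2
      g[terms[i]] <- g[terms[i]] + 1 / S
      out$std_error[i] <- sqrt(drop(t(g) %*% vc[names(est), names(est)] %*% g))
    }
  }
  attr(out, "denominator") <- denominator
  attr(out, "sigma_g2") <- sum(est[intersect(c("additive", "dominance", "aa"),
                                             names(est))])
  out
}
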