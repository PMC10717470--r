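#' Likelihood-ratio test between nested REML fits
#'
#' LRT = -2 (logL_reduced - logL_complete), referred to a chi-square with
#' degrees of freedom equal to the difference in variance-parameter counts.
#' Fits must share the fixed structure (in particular, both include or both
#' exclude the inbreeding covariate) and the reduced model's random terms
#' must nest in the complete model's. A numerically negative statistic
#' (optimizer noise) is clipped at zero with a message. The chi-square
#' reference is conservative when the tested component sits on the boundary
#' of the parameter space.
#'
#' @param reduced,complete `reml_fit`s on the same data.
#' @return A tibble: `statistic`, `df`, `p_value`, `significant` (at 0.05).
#' @export
likelihood_ratio_test <- function(reduced, complete) {
  stopifnot(inherits(reduced, "reml_fit"), inherits(complete, "reml_fit"))
  if (!all(reduced$spec$random %in% complete$spec$random)) {
    abort("models are not nested: reduced terms must be a subset.")
  }
  same_fixed <- identical(reduced$spec$fixed, complete$spec$fixed) &&
    identical(reduced$spec$covariates, complete$spec$covariates) &&
    identical(reduced$spec$inbreeding, complete$spec$inbreeding)
  if (!same_fixed) {
    abort("fixed structures differ; REML likelihoods are not comparable.")
  }
  if (reduced$n_records != complete$n_records) {
    abort("fits use different data.")
  }
  stat <- -2 * (reduced$reml_loglik - complete$reml_loglik)
  if (stat < 0) {
    inform(sprintf("negative LRT statistic (%.3e) clipped at 0 (optimizer noise).",
                   stat))
    stat <- 0
  }
  df <- complete$n_params - reduced$n_params
  p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else 1
  tibble::tibble(reduced = reduced$spec$name, complete = complete$spec$name,
                 statistic = stat, df = df, p_value = p,
                 significant = p < 0.05)
}

#' Spearman rank correlation between two GEBV vectors
#'
#' Rank correlation with average ranks for ties, used to quantify animal
#' re-ranking between models.
#'
#' @param gebv_a,gebv_b Aligned per-animal GEBV vectors (length >= 2).
#' @return The correlation in [-1, 1].
#' @export
spearman_rank_correlation <- function(gebv_a, gebv_b) {
  if (length(gebv_a) != length(gebv_b) || length(gebv_a) < 2L) {
    abort("need two aligned vectors of length >= 2.")
  }
  if (sd(gebv_a) == 0 || sd(gebv_b) == 0) {
    abort("constant GEBV vector: rank correlation undefined.")
  }
  cor(gebv_a, gebv_b, method = "spearman")
}

#' Overlap of top-ranked animals between two models
#'
#' For each selection fraction, the ceiling(fraction * n) highest-GEBV
#' animals are selected under each vector (ties broken by stable animal-id
#' order) and the overlap reported as a percentage of the selection size.
#'
#' @param gebv_ref,gebv_alt Named, aligned GEBV vectors.
#' @param fractions Selection fractions in (0, 1].
#' @param direction `"high"` selects the largest GEBVs, `"low"` the
#'   smallest.
#' @return A tibble `fraction`, `n_selected`, `overlap_pct`.
#' @export
top_fraction_overlap <- function(gebv_ref, gebv_alt,
                                 fractions = c(0.01, 0.05, 0.10, 0.20),
                                 direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (any(fractions <= 0 | fractions > 1)) {
    abort("fractions must lie in (0, 1].")
  }
  ids <- names(gebv_ref)
  if (is.null(ids)) ids <- as.character(seq_along(gebv_ref))
  if (length(gebv_alt) != length(gebv_ref)) abort("vectors must be aligned.")
  n <- length(gebv_ref)
  sgn <- if (direction == "high") -1 else 1
  ord_ref <- order(sgn * gebv_ref, ids)
  ord_alt <- order(sgn * gebv_alt, ids)
  purrr::map_dfr(fractions, function(fr) {
    size <- ceiling(fr * n)
    top_ref <- ids[ord_ref[seq_len(size)]]
    top_alt <- ids[ord_alt[seq_len(size)]]
    tibble::tibble(fraction = fr, n_selected = size,
                   overlap_pct = 100 * length(intersect(top_ref, top_alt)) / size)
  })
}

#' Assemble a model-comparison report
#'
#' Collects, across a battery of fits on the same data: the AIC table,
#' likelihood-ratio tests of each model against the reference that shares
#' its fixed structure, Spearman correlations of GEBVs against the
#' reference model, and top-fraction selected-animal overlaps.
#' Non-converged fits are kept in the AIC table with a flag but excluded
#' from the LRT entries.
#'
#' @param fits List of `reml_fit`s (named or not).
#' @param reference Name of the reference model (must be among the fits).
#' @param fractions Selection fractions for the overlap table.
#' @param validation Optional named list of `lr_stats` to append.
#' @return A `comparison_report` list of tibbles: `aic_table`,
#'   `lrt_entries`, `spearman`, `overlap`, `validation`.
#' @export
comparison_report <- function(fits, reference,
                              fractions = c(0.01, 0.05, 0.10, 0.20),
                              validation = NULL) {
  if (!length(fits)) abort("empty fit list.")
  names(fits) <- vapply(fits, function(f) f$spec$name, "")
  if (!reference %in% names(fits)) {
    abort(sprintf("reference model '%s' not among the fits.", reference))
  }
  ref <- fits[[reference]]
  aic_table <- dplyr::bind_rows(lapply(fits, glance))
  aic_table <- dplyr::arrange(aic_table, .data$aic)

  lrt <- list()
  spearman <- list()
  overlap <- list()
  u_ref <- gebv(ref)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (nm != reference && f$converged && ref$converged &&
        all(ref$spec$random %in% f$spec$random) &&
        identical(ref$spec$inbreeding, f$spec$inbreeding)) {
      lrt[[nm]] <- likelihood_ratio_test(ref, f)
    }
    if (f$converged) {
      u <- gebv(f)
      spearman[[nm]] <- tibble::tibble(model = nm,
                                       rho = spearman_rank_correlation(u_ref, u))
      overlap[[nm]] <- dplyr::mutate(
        top_fraction_overlap(u_ref, u, fractions), model = nm, .before = 1L)
    }
  }
  out <- list(
    reference = reference,
    aic_table = aic_table,
    lrt_entries = dplyr::bind_rows(lrt),
    spearman = dplyr::bind_rows(spearman),
    overlap = dplyr::bind_rows(overlap)
  )
  if (!is.null(validation)) {
    out$validation <- dplyr::bind_rows(
      purrr::imap(validation, function(v, nm) {
        dplyr::mutate(v$aggregate, model = nm, .before = 1L)
      }))
  }
  structure(out, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report: reference %s, %d model(s)>\n",
              x$reference, nrow(x$aic_table)))
  cat("AIC table:\n"); print(x$aic_table)
  if (nrow(x$lrt_entries)) { cat("LRT vs reference:\n"); print(x$lrt_entries) }
  invisible(x)
}
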