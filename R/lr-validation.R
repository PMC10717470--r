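# Linear Regression (LR) method of predictive-ability assessment: compare
# breeding values predicted from partial data (focal animals' records
# masked) with those from the whole data.

#' Assign animals to cross-validation folds
#'
#' Uniform random partition of the animal set into k folds whose sizes
#' differ by at most one; all records of an animal share its fold.
#'
#' @param animal_ids Character vector of animal ids.
#' @param k Number of folds (>= 2, <= number of animals).
#' @param seed Integer seed.
#' @return A tibble `id`, `fold`.
#' @export
make_folds <- function(animal_ids, k = 10L, seed = 1L) {
  k <- check_count(k, "k", min = 2L)
  animal_ids <- unique(as.character(animal_ids))
  if (k > length(animal_ids)) abort("more folds than animals.")
  with_seed(seed, {
    shuffled <- sample(animal_ids)
    tibble::tibble(id = shuffled,
                   fold = rep_len(seq_len(k), length(shuffled)))[
                     order(match(shuffled, animal_ids)), ]
  })
}

#' LR-method statistics for one partial/whole comparison
#'
#' Bias is the mean difference of partial and whole predictions, dispersion
#' the slope of the regression of whole on partial predictions
#' (cov(u_p, u_w)/var(u_p)), and accuracy sqrt(cov(u_p, u_w) /
#' ((1 - F_bar) * sigma2_a)) with F_bar the mean inbreeding of the
#' focal animals and sigma2_a the whole-data additive variance estimate. A
#' negative covariance leaves the accuracy undefined (NA, with a message).
#'
#' @param u_partial,u_whole Aligned per-animal GEBV vectors.
#' @param F_bar Mean inbreeding coefficient of the focal animals.
#' @param sigma_a2 Additive genetic variance from the whole-data fit.
#' @return A one-row tibble: `bias`, `dispersion`, `accuracy`, `n`.
#' @export
#' @examples
#' u <- rnorm(50)
#' lr_statistics(u, u, F_bar = 0, sigma_a2 = 1)
lr_statistics <- function(u_partial, u_whole, F_bar = 0, sigma_a2) {
  if (length(u_partial) != length(u_whole)) {
    abort("partial and whole GEBV vectors must be aligned.")
  }
  if (!is.null(names(u_partial)) && !is.null(names(u_whole)) &&
      !identical(names(u_partial), names(u_whole))) {
    abort("partial and whole GEBV vectors name different animals.")
  }
  vp <- var(u_partial)
  if (!is.finite(vp) || vp == 0) abort("zero variance of partial GEBVs.")
  cv <- cov(u_partial, u_whole)
  acc <- NA_real_
  if (cv < 0) {
    inform("negative partial/whole covariance: accuracy undefined (NA).")
  } else {
    acc <- sqrt(cv / ((1 - F_bar) * sigma_a2))
  }
  tibble::tibble(bias = mean(u_partial) - mean(u_whole),
                 dispersion = cv / vp,
                 accuracy = acc,
                 n = length(u_partial))
}

#' Cross-validated predictive ability by the LR method
#'
#' Fits the model on the whole data, then for each fold refits it with all
#' records of that fold's animals removed (variance components
#' re-estimated), and compares the masked animals' partial GEBVs with their
#' whole-data GEBVs. Per-fold statistics are averaged arithmetically. The
#' accuracy denominator uses the whole-data additive variance and the mean
#' inbreeding of the masked animals (zero when no inbreeding source is
#' given). Folds whose partial fit does not converge are skipped with a
#' message and flagged.
#'
#' @inheritParams build_design
#' @param folds Fold assignment from [make_folds()].
#' @param ... Passed on to [fit_reml()].
#' @return An `lr_stats` object: `per_fold` tibble, `aggregate` one-row
#'   tibble, the whole-data `fit`, and `sigma_a2`.
#' @export
cross_validate <- function(phenotypes, spec, grms, inbreeding = NULL,
                           folds, ...) {
  ds <- build_design(phenotypes, spec, grms, inbreeding)
  whole <- fit_reml(ds, ...)
  if (!whole$converged) abort("whole-data fit did not converge.")
  u_w <- gebv(whole)
  sigma_a2 <- whole$variances$estimate[whole$variances$term == "additive"]
  fmap <- if (!is.null(inbreeding)) setNames(inbreeding$F, inbreeding$id)

  per_fold <- list()
  skipped <- integer()
  for (kf in sort(unique(folds$fold))) {
    masked <- folds$id[folds$fold == kf]
    keep <- !(phenotypes$animal %in% masked)
    ds_p <- build_design(phenotypes[keep, , drop = FALSE], spec, grms, inbreeding)
    fit_p <- tryCatch(fit_reml(ds_p, ...), error = function(e) NULL)
    if (is.null(fit_p) || !fit_p$converged) {
      inform(sprintf("fold %d: partial fit failed to converge; skipped.", kf))
      skipped <- c(skipped, kf)
      next
    }
    u_p <- gebv(fit_p)[masked]
    F_bar <- if (!is.null(fmap)) mean(fmap[masked]) else 0
    st <- lr_statistics(u_p, u_w[masked], F_bar = F_bar, sigma_a2 = sigma_a2)
    per_fold[[length(per_fold) + 1L]] <-
      dplyr::mutate(st, fold = kf, F_bar = F_bar, .before = 1L)
  }
  if (!length(per_fold)) abort("no fold produced a converged partial fit.")
  per_fold <- dplyr::bind_rows(per_fold)
  aggregate <- dplyr::summarise(
    per_fold,
    bias = mean(.data$bias), dispersion = mean(.data$dispersion),
    accuracy = mean(.data$accuracy, na.rm = TRUE),
    F_bar = mean(.data$F_bar), n_folds = dplyr::n()
  )
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 fit = whole, sigma_a2 = sigma_a2, skipped_folds = skipped,
                 model = spec$name),
            class = "lr_stats")
}

#' @export
print.lr_stats <- function(x, ...) {
  cat(sprintf("<lr_stats %s over %d fold(s)>\n", x$model, nrow(x$per_fold)))
  print(x$aggregate)
  invisible(x)
}
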