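#' Tidy a REML fit
#'
#' One row per estimated variance component (and, with `effects =
#' "fixed"`, per fixed-effect coefficient), in broom convention.
#'
#' @param x A `reml_fit`.
#' @param effects `"variances"` (default) or `"fixed"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.reml_fit <- function(x, effects = c("variances", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    return(dplyr::mutate(x$fixed_solutions, model = x$spec$name,
                         .before = 1L))
  }
  dplyr::mutate(x$variances, model = x$spec$name, .before = 1L)
}

#' One-line summary of a REML fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, log-likelihood, AIC, parameter count,
#'   convergence flag, iterations, record and animal counts.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(model = x$spec$name, reml_loglik = x$reml_loglik,
                 aic = x$aic, n_params = x$n_params,
                 converged = x$converged, n_iterations = x$n_iterations,
                 n_records = x$n_records, n_animals = x$n_animals,
                 n_at_boundary = length(x$at_boundary))
}

#' Plot variance components of one or more fits
#'
#' @param object A `reml_fit`.
#' @param ... Further `reml_fit`s to overlay.
#' @return A ggplot: component estimates with +/- 1 SE bars, faceted by
#'   model when several fits are given.
#' @export
autoplot.reml_fit <- function(object, ...) {
  fits <- c(list(object), Filter(function(f) inherits(f, "reml_fit"), list(...)))
  tab <- dplyr::bind_rows(lapply(fits, tidy))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$std_error,
                                        ymax = .data$estimate + .data$std_error),
                           width = 0.25, na.rm = TRUE) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = NULL, y = "variance estimate") +
    ggplot2::theme_minimal()
}

#' Tidy LR cross-validation statistics
#'
#' @param x An `lr_stats` object from [cross_validate()] or
#'   [lr_statistics()].
#' @param ... Unused.
#' @return Per-fold tibble with the aggregate row appended.
#' @export
tidy.lr_stats <- function(x, ...) {
  dplyr::bind_rows(x$per_fold,
                   dplyr::mutate(x$aggregate, fold = NA_integer_, .before = 1L))
}

#' @export
glance.lr_stats <- function(x, ...) x$aggregate

#' Plot LR-method validation statistics
#'
#' Three panels — bias, dispersion and accuracy — with their per-fold spread,
#' plus reference lines at the ideal values (0, 1 and the fold mean).
#'
#' @param object An `lr_stats` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lr_stats <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold,
                              cols = c("bias", "dispersion", "accuracy"),
                              names_to = "statistic", values_to = "value")
  ref <- tibble::tibble(statistic = c("bias", "dispersion"), value = c(0, 1))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$statistic, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$value),
                        linetype = 2, colour = "red3") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
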