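#' Simulate a multi-generation pedigree
#'
#' Generates a topologically ordered pedigree by random mating within
#' discrete generations. A controllable fraction of matings pairs full sibs,
#' which creates inbred offspring (pedigree F = 0.25 from one full-sib
#' mating) for exercising inbreeding-depression covariates and genomic
#' inbreeding estimators.
#'
#' @param n_founders Number of unrelated, non-inbred founder animals (>= 2).
#' @param n_generations Number of discrete offspring generations (0 returns
#'   founders only).
#' @param matings_per_generation Matings performed in each generation.
#' @param offspring_per_mating Offspring produced per mating.
#' @param full_sib_mating_fraction Proportion of matings that pair two full
#'   sibs from the previous generation (when such a pair exists).
#' @param seed Integer seed; the same seed reproduces the pedigree exactly.
#'
#' @return A tibble of class `ped_tbl` with columns `id`, `sire`, `dam`
#'   (parents `NA` for founders) and `generation`, in topological order.
#' @export
#' @examples
#' ped <- simulate_pedigree(10, 2, matings_per_generation = 5, seed = 1)
#' head(ped)
simulate_pedigree <- function(n_founders,
                              n_generations = 0L,
                              matings_per_generation = 1L,
                              offspring_per_mating = 2L,
                              full_sib_mating_fraction = 0,
                              seed = 1L) {
  n_founders <- check_count(n_founders, "n_founders", min = 2L)
  n_generations <- check_count(n_generations, "n_generations", min = 0L)
  if (n_generations > 0L) {
    matings_per_generation <- check_count(matings_per_generation,
                                          "matings_per_generation")
    offspring_per_mating <- check_count(offspring_per_mating,
                                        "offspring_per_mating")
  }
  check_proportion(full_sib_mating_fraction, "full_sib_mating_fraction")

  with_seed(seed, {
    id <- paste0("F", seq_len(n_founders))
    rec <- tibble::tibble(id = id, sire = NA_character_, dam = NA_character_,
                          generation = 0L)
    prev <- rec
    counter <- 0L
    for (g in seq_len(n_generations)) {
      offspring <- list()
      # full-sib groups of the previous generation, usable for sib matings
      has_par <- !is.na(prev$sire) & !is.na(prev$dam)
      sib_groups <- split(prev$id[has_par],
                          paste(prev$sire[has_par], prev$dam[has_par]))
      sib_groups <- sib_groups[lengths(sib_groups) >= 2L]
      for (m in seq_len(matings_per_generation)) {
        use_sibs <- length(sib_groups) > 0L &&
          runif(1) < full_sib_mating_fraction
        if (use_sibs) {
          grp <- sib_groups[[sample.int(length(sib_groups), 1L)]]
          pair <- sample(grp, 2L)
        } else {
          pair <- sample(prev$id, 2L)
        }
        for (k in seq_len(offspring_per_mating)) {
          counter <- counter + 1L
          offspring[[length(offspring) + 1L]] <- tibble::tibble(
            id = sprintf("G%d_%d", g, counter),
            sire = pair[1L], dam = pair[2L], generation = g
          )
        }
      }
      offspring <- dplyr::bind_rows(offspring)
      rec <- dplyr::bind_rows(rec, offspring)
      prev <- offspring
    }
    new_ped_tbl(rec)
  })
}

new_ped_tbl <- function(x) {
  stopifnot(all(c("id", "sire", "dam") %in% names(x)))
  if (!"generation" %in% names(x)) x$generation <- NA_integer_
  structure(x, class = c("ped_tbl", class(tibble::as_tibble(x))))
}

#' Coerce a data frame to a validated pedigree
#'
#' Checks topological order (every named parent occurs earlier as an animal),
#' uniqueness of ids, and absence of self-ancestry. Parent codes `NA`, `""`
#' and `"0"` all denote an unknown parent.
#'
#' @param x Data frame with columns `id`, `sire`, `dam`.
#' @return A `ped_tbl` tibble in the input order.
#' @export
as_pedigree <- function(x) {
  x <- tibble::as_tibble(x)
  for (col in c("id", "sire", "dam")) {
    if (!col %in% names(x)) abort(sprintf("pedigree needs a `%s` column.", col))
    x[[col]] <- as.character(x[[col]])
  }
  x$sire[x$sire %in% c("", "0")] <- NA_character_
  x$dam[x$dam %in% c("", "0")] <- NA_character_
  if (anyDuplicated(x$id)) abort("duplicated animal ids in pedigree.")
  seen <- character(0)
  for (i in seq_len(nrow(x))) {
    for (p in c(x$sire[i], x$dam[i])) {
      if (!is.na(p) && !p %in% seen) {
        abort(sprintf(
          "pedigree is not topologically ordered (or cyclic): parent '%s' of '%s' not seen earlier.",
          p, x$id[i]))
      }
    }
    seen <- c(seen, x$id[i])
  }
  if (!"generation" %in% names(x)) {
    gen <- setNames(integer(nrow(x)), x$id)
    for (i in seq_len(nrow(x))) {
      par <- c(x$sire[i], x$dam[i])
      par <- par[!is.na(par)]
      gen[i] <- if (length(par)) max(gen[par]) + 1L else 0L
    }
    x$generation <- unname(gen)
  }
  new_ped_tbl(x)
}

#' Pedigree inbreeding coefficients
#'
#' Computes Wright's inbreeding coefficient F for every animal by the
#' tabular method: the numerator relationship matrix A is built recursively
#' in topological order and F is its diagonal minus one. Founders have F = 0.
#'
#' @param ped A pedigree (`ped_tbl` or coercible data frame).
#' @return A tibble with columns `id`, `F` and attribute `source =
#'   "pedigree"`; mean F is available via `attr(, "mean_F")`.
#' @export
pedigree_inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  A <- matrix(0, n, n)
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  for (i in seq_len(n)) {
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (s[i] > 0L) A[j, s[i]] else 0) +
                     (if (d[i] > 0L) A[j, d[i]] else 0))
      A[j, i] <- A[i, j] <- aj
    }
  }
  out <- tibble::tibble(id = ped$id, F = diag(A) - 1)
  attr(out, "source") <- "pedigree"
  attr(out, "mean_F") <- mean(out$F)
  out
}

#' Genomic inbreeding coefficients
#'
#' The VanRaden-consistent genomic inbreeding estimator: F_i = diag(G_A)_i -
#' 1, which may be slightly negative for animals less homozygous than the
#' Hardy-Weinberg expectation at observed frequencies.
#'
#' @param ga An additive genomic relationship matrix (`grm` of kind `"A"`).
#' @return A tibble with columns `id`, `F`; attribute `source = "genomic"`.
#' @export
genomic_inbreeding <- function(ga) {
  if (!inherits(ga, "grm") || attr(ga, "kind") != "A") {
    abort("`ga` must be an additive relationship matrix (kind \"A\").")
  }
  out <- tibble::tibble(id = rownames(ga), F = unname(diag(ga)) - 1)
  attr(out, "source") <- "genomic"
  attr(out, "mean_F") <- mean(out$F)
  out
}
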