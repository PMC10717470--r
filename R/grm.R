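new_grm <- function(values, kind, sample_ids) {
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(values, kind = kind, class = c("grm", "matrix", "array"))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm kind=%s: %d x %d, mean diag %.4f>\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' Additive genomic relationship matrix (VanRaden)
#'
#' G_A = M M' / (2 * sum(p_i q_i)), where M codes genotypes A1A1, A1A2, A2A2
#' as (2 - 2p_i), (1 - 2p_i), (-2p_i), i.e. allele dosage centred at twice
#' the allele frequency. With frequencies observed in the analysed sample
#' the columns of M are mean-centred, so every row of G_A sums to zero.
#' Missing calls are imputed at the dosage expectation 2p_i (a centred
#' contribution of zero).
#'
#' @param g A [genotype_matrix()].
#' @param freqs Allele frequencies as returned by [allele_frequencies()];
#'   defaults to frequencies observed in `g`.
#' @return A `grm` of kind `"A"`.
#' @export
additive_grm <- function(g, freqs = allele_frequencies(g)) {
  stopifnot(inherits(g, "genotype_matrix"))
  check_freqs(freqs, g)
  denom <- 2 * sum(freqs$p * (1 - freqs$p))
  if (denom <= 0) abort("sum(p*q) is zero: no polymorphic SNPs.")
  M <- sweep(imputed_dosage(g, freqs), 2L, 2 * freqs$p)
  new_grm(tcrossprod(M) / denom, "A", rownames(g))
}

#' Dominance genomic relationship matrix (Vitezica)
#'
#' G_D = W W' / (4 * sum(p_i^2 q_i^2)), with W coding A1A1, A1A2, A2A2 as
#' (-2 q_i^2), (2 p_i q_i), (-2 p_i^2). Under Hardy-Weinberg proportions
#' this coding is orthogonal to the additive dosage, partitioning dominance
#' variance cleanly from additive variance. Missing calls contribute the
#' Hardy-Weinberg expectation of W, which is zero.
#'
#' @inheritParams additive_grm
#' @return A `grm` of kind `"D"`.
#' @export
dominance_grm <- function(g, freqs = allele_frequencies(g)) {
  stopifnot(inherits(g, "genotype_matrix"))
  check_freqs(freqs, g)
  denom <- 4 * sum(freqs$p^2 * (1 - freqs$p)^2)
  if (denom <= 0) abort("sum(p^2*q^2) is zero: no polymorphic SNPs.")
  n <- nrow(g); m <- ncol(g)
  X <- unclass(g)
  W <- matrix(0, n, m, dimnames = dimnames(g))
  p <- freqs$p; q <- 1 - freqs$p
  # per-genotype codes, recycled row-wise via indexing
  hom1 <- matrix(-2 * q^2, n, m, byrow = TRUE)
  het <- matrix(2 * p * q, n, m, byrow = TRUE)
  hom2 <- matrix(-2 * p^2, n, m, byrow = TRUE)
  W[which(X == 2)] <- hom1[which(X == 2)]
  W[which(X == 1)] <- het[which(X == 1)]
  W[which(X == 0)] <- hom2[which(X == 0)]
  # missing stays 0 = E[W] under HWE
  new_grm(tcrossprod(W) / denom, "D", rownames(g))
}

#' Epistatic relationship matrices via Hadamard products
#'
#' G_AA = (G_A o G_A) / (tr(G_A o G_A) / n), and analogously G_AD from
#' G_A o G_D and G_DD from G_D o G_D, where `o` is the elementwise
#' (Hadamard) product. The divisor rescales the matrix so its trace equals
#' the number of animals, putting the attached variance component on the
#' same per-animal scale as the additive and dominance components.
#'
#' @param left,right Input `grm`s (kinds must match `kind`: AA needs A and
#'   A, AD needs A and D, DD needs D and D; order of A/D is free).
#' @param kind `"AA"`, `"AD"` or `"DD"`.
#' @return A `grm` of the requested kind with trace exactly n.
#' @export
epistatic_grm <- function(left, right, kind = c("AA", "AD", "DD")) {
  kind <- match.arg(kind)
  stopifnot(inherits(left, "grm"), inherits(right, "grm"))
  need <- switch(kind, AA = c("A", "A"), AD = c("A", "D"), DD = c("D", "D"))
  got <- sort(c(attr(left, "kind"), attr(right, "kind")))
  if (!identical(sort(need), got)) {
    abort(sprintf("kind %s requires inputs of kind %s and %s.",
                  kind, need[1L], need[2L]))
  }
  if (!identical(rownames(left), rownames(right))) {
    abort("sample orderings of the two matrices differ.")
  }
  raw <- unclass(left) * unclass(right)
  tr <- sum(diag(raw))
  if (tr <= 0) abort("zero trace of the Hadamard product.")
  new_grm(raw * (nrow(raw) / tr), kind, rownames(left))
}

#' Project a relationship matrix onto the positive semidefinite cone
#'
#' Hadamard-product matrices can be numerically indefinite; this clips
#' eigenvalues below `-tol_frac * max(eigenvalue)` at zero and records the
#' raw minimum eigenvalue as an attribute.
#'
#' @param x A `grm`.
#' @param tol_frac Relative clipping tolerance.
#' @return The clipped `grm`; `attr(, "raw_min_eigenvalue")` holds the
#'   pre-clipping minimum.
#' @export
grm_psd <- function(x, tol_frac = 1e-8) {
  stopifnot(inherits(x, "grm"))
  out <- psd_clip(unclass(x), tol_frac)
  res <- new_grm(out, attr(x, "kind"), rownames(x))
  attr(res, "raw_min_eigenvalue") <- attr(out, "raw_min_eigenvalue")
  res
}

#' Build the full set of relationship matrices for a model battery
#'
#' Convenience wrapper returning the structures every named model variant
#' can reference: A, D, AA, AD, DD keyed by the random-term labels they
#' serve.
#'
#' @param g A [genotype_matrix()].
#' @param freqs Optional allele frequencies (defaults to observed).
#' @param kinds Which matrices to build.
#' @return A named list: `additive`, `dominance`, `aa`, `ad`, `dd` (subset
#'   per `kinds`).
#' @export
build_grms <- function(g, freqs = allele_frequencies(g),
                       kinds = c("A", "D", "AA", "AD", "DD")) {
  out <- list()
  GA <- if (any(kinds %in% c("A", "AA", "AD"))) additive_grm(g, freqs)
  GD <- if (any(kinds %in% c("D", "AD", "DD"))) dominance_grm(g, freqs)
  if ("A" %in% kinds) out$additive <- GA
  if ("D" %in% kinds) out$dominance <- GD
  if ("AA" %in% kinds) out$aa <- epistatic_grm(GA, GA, "AA")
  if ("AD" %in% kinds) out$ad <- epistatic_grm(GA, GD, "AD")
  if ("DD" %in% kinds) out$dd <- epistatic_grm(GD, GD, "DD")
  out
}

check_freqs <- function(freqs, g) {
  if (!all(c("snp", "p") %in% names(freqs)) || nrow(freqs) != ncol(g)) {
    abort("`freqs` must be an allele-frequency table with one row per SNP.")
  }
  if (any(freqs$p <= 0 | freqs$p >= 1)) {
    abort("allele frequencies must lie strictly in (0, 1); drop monomorphic SNPs first.")
  }
  invisible(freqs)
}
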