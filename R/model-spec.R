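#' Model specification for variance-component fits
#'
#' A declarative description of one mixed model: its fixed factors,
#' covariates (including, optionally, the inbreeding coefficient fitted as
#' an inbreeding-depression covariate), and ordered random genetic terms,
#' each tied to a relationship-matrix kind. The residual is implicit.
#'
#' The 16-name catalogue follows the standard naming scheme for these model
#' batteries: `A` additive, `I` inbreeding covariate, `D` dominance, `E`
#' additive-by-additive epistasis (`E1`), `E2` adds additive-by-dominance,
#' `E3` adds dominance-by-dominance, `pe` a permanent environmental effect
#' for repeated records. So e.g. `MAIDE2` fits inbreeding + additive +
#' dominance + aa + ad, and `MAIDEpe` fits inbreeding + additive + dominance
#' + aa + permanent environment.
#'
#' @param name Catalogue name (see Details) or any label for a custom spec.
#' @param fixed List of fixed factors; each element is a column name or a
#'   character vector of column names whose observed cross-combinations form
#'   one concatenated factor.
#' @param covariates Character vector of numeric covariate columns.
#' @param random Character vector of random-term labels from
#'   `c("additive", "dominance", "aa", "ad", "dd", "pe")`; `NULL` uses the
#'   catalogue definition of `name`.
#' @param inbreeding Logical: fit the inbreeding coefficient as a covariate;
#'   `NULL` uses the catalogue definition.
#' @param response Name of the trait column (default `"y"`).
#' @return A `model_spec` object.
#' @export
#' @examples
#' model_spec("MADE1")
#' model_spec("custom", random = c("additive", "pe"), inbreeding = TRUE)
model_spec <- function(name, fixed = list(), covariates = character(),
                       random = NULL, inbreeding = NULL, response = "y") {
  cat_entry <- model_catalogue()[[name]]
  if (is.null(random)) {
    if (is.null(cat_entry)) {
      abort(sprintf("'%s' is not a catalogue model; supply `random` explicitly.", name))
    }
    random <- cat_entry$random
  }
  if (is.null(inbreeding)) {
    inbreeding <- if (is.null(cat_entry)) FALSE else cat_entry$inbreeding
  }
  valid <- c("additive", "dominance", "aa", "ad", "dd", "pe")
  if (!all(random %in% valid) || anyDuplicated(random)) {
    abort("random terms must be unique labels from additive/dominance/aa/ad/dd/pe.")
  }
  if (is.character(fixed)) fixed <- as.list(fixed)
  structure(list(name = name, fixed = fixed, covariates = covariates,
                 random = random, inbreeding = inbreeding,
                 response = response),
            class = "model_spec")
}

#' The named model catalogue
#'
#' @return Named list mapping each catalogue model name to its random terms
#'   and inbreeding flag.
#' @export
model_catalogue <- function() {
  base <- list(
    MA     = list(random = "additive", inbreeding = FALSE),
    MAI    = list(random = "additive", inbreeding = TRUE),
    MAE    = list(random = c("additive", "aa"), inbreeding = FALSE),
    MAIE   = list(random = c("additive", "aa"), inbreeding = TRUE),
    MAD    = list(random = c("additive", "dominance"), inbreeding = FALSE),
    MAID   = list(random = c("additive", "dominance"), inbreeding = TRUE),
    MADE1  = list(random = c("additive", "dominance", "aa"), inbreeding = FALSE),
    MAIDE1 = list(random = c("additive", "dominance", "aa"), inbreeding = TRUE),
    MADE2  = list(random = c("additive", "dominance", "aa", "ad"), inbreeding = FALSE),
    MAIDE2 = list(random = c("additive", "dominance", "aa", "ad"), inbreeding = TRUE),
    MADE3  = list(random = c("additive", "dominance", "aa", "ad", "dd"), inbreeding = FALSE),
    MAIDE3 = list(random = c("additive", "dominance", "aa", "ad", "dd"), inbreeding = TRUE),
    MAIpe   = list(random = c("additive", "pe"), inbreeding = TRUE),
    MAIDpe  = list(random = c("additive", "dominance", "pe"), inbreeding = TRUE),
    MAIEpe  = list(random = c("additive", "aa", "pe"), inbreeding = TRUE),
    MAIDEpe = list(random = c("additive", "dominance", "aa", "pe"), inbreeding = TRUE)
  )
  base
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s: random = %s%s>\n", x$name,
              paste(x$random, collapse = " + "),
              if (x$inbreeding) " + inbreeding covariate" else ""))
  invisible(x)
}

#' Build the design system for a REML fit
#'
#' Assembles y, the fixed-effect design X (intercept + dummy-coded factors
#' with the reference level dropped + covariates + optional inbreeding
#' coefficient), the record-to-animal incidence Z, and the per-term
#' covariance matrices. Concatenated factors are the observed
#' cross-combinations of the named columns. Single-level factors are dropped
#' with a message; rank-deficient columns of X are dropped via a QR check.
#'
#' @param phenotypes Tibble with columns `animal`, the response, factor and
#'   covariate columns.
#' @param spec A [model_spec()].
#' @param grms Named list of relationship matrices (labels `additive`,
#'   `dominance`, `aa`, `ad`, `dd`) as from [build_grms()]; the `pe` term
#'   needs no matrix (identity over animals).
#' @param inbreeding Inbreeding tibble (`id`, `F`) as from
#'   [pedigree_inbreeding()] or [genomic_inbreeding()]; required iff the
#'   spec includes the covariate.
#' @return A `design_system` list: `y`, `X`, `Z`, `G` (per-term n x n
#'   covariances, identity for `pe`), `animal_ids`, `spec`.
#' @export
build_design <- function(phenotypes, spec, grms, inbreeding = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  pt <- tibble::as_tibble(phenotypes)
  if (!"animal" %in% names(pt)) abort("phenotypes need an `animal` column.")
  if (!spec$response %in% names(pt)) {
    abort(sprintf("response column '%s' not found.", spec$response))
  }
  y <- pt[[spec$response]]
  if (any(!is.finite(y))) abort("trait values must be finite.")
  pt$animal <- as.character(pt$animal)

  # animal universe and per-term covariance structures
  genetic <- setdiff(spec$random, "pe")
  ids <- NULL
  for (term in genetic) {
    if (is.null(grms[[term]])) {
      abort(sprintf("no relationship matrix supplied for term '%s'.", term))
    }
    if (is.null(ids)) ids <- rownames(grms[[term]])
    else if (!identical(ids, rownames(grms[[term]]))) {
      abort("relationship matrices have inconsistent sample orderings.")
    }
  }
  if (is.null(ids)) ids <- unique(pt$animal)
  if (!all(pt$animal %in% ids)) {
    abort("phenotyped animals missing from the relationship matrices.")
  }
  if ("pe" %in% spec$random && max(table(pt$animal)) < 2L) {
    abort("a permanent environmental term requires repeated records.")
  }

  N <- nrow(pt); n <- length(ids)
  Z <- matrix(0, N, n, dimnames = list(NULL, ids))
  Z[cbind(seq_len(N), match(pt$animal, ids))] <- 1

  # fixed design
  X <- matrix(1, N, 1, dimnames = list(NULL, "(Intercept)"))
  for (fac in spec$fixed) {
    lab <- paste(fac, collapse = ".")
    missing_cols <- setdiff(fac, names(pt))
    if (length(missing_cols)) {
      abort(sprintf("fixed factor column(s) not found: %s",
                    paste(missing_cols, collapse = ", ")))
    }
    lev <- interaction(pt[fac], drop = TRUE, sep = ":")
    if (nlevels(lev) < 2L) {
      inform(sprintf("fixed factor '%s' has a single level; dropped.", lab))
      next
    }
    mm <- model.matrix(~ lev)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(lab, levels(lev)[-1L])
    X <- cbind(X, mm)
  }
  for (cv in spec$covariates) {
    if (!cv %in% names(pt)) abort(sprintf("covariate '%s' not found.", cv))
    X <- cbind(X, setNames(as.matrix(pt[[cv]]), NULL))
    colnames(X)[ncol(X)] <- cv
  }
  if (spec$inbreeding) {
    if (is.null(inbreeding)) {
      abort(sprintf("model %s includes the inbreeding covariate: supply `inbreeding`.",
                    spec$name))
    }
    fmap <- setNames(inbreeding$F, inbreeding$id)
    if (!all(pt$animal %in% names(fmap))) {
      abort("inbreeding vector does not cover all phenotyped animals.")
    }
    X <- cbind(X, f = unname(fmap[pt$animal]))
  } else if (!is.null(inbreeding)) {
    inform(sprintf("model %s has no inbreeding covariate; `inbreeding` ignored.",
                   spec$name))
  }
  # drop rank-deficient columns
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- colnames(X)[-keep]
    inform(sprintf("dropped rank-deficient fixed column(s): %s",
                   paste(dropped, collapse = ", ")))
    X <- X[, sort(keep), drop = FALSE]
  }

  G <- list()
  for (term in spec$random) {
    G[[term]] <- if (term == "pe") diag(n) else unclass(grms[[term]])
  }
  structure(list(y = y, X = X, Z = Z, G = G, animal_ids = ids, spec = spec,
                 n_records = N, n_animals = n),
            class = "design_system")
}
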