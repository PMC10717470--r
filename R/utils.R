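# Internal helpers shared across modules.

# Run `code` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so package functions never disturb the session.
with_seed <- function(seed, code) {
  # force the seed promise first: callers may pass seed = <RNG draw>, which
  # must advance the caller's stream before we snapshot and restore it
  seed <- as.integer(seed)
  if (!is.null(old <- get0(".Random.seed", globalenv(), ifnotfound = NULL))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed; keeps every stage of a
# pipeline independently reproducible while staying inside 32-bit range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single proportion in [0, 1].", name))
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

# Symmetric factorisation L with L L' ~= S, via eigen-decomposition with
# negative eigenvalues clipped at zero. Hadamard-product relationship
# matrices are only numerically semidefinite, so clipping is routine.
sym_factor <- function(S, warn_label = NULL) {
  ee <- eigen(S, symmetric = TRUE)
  vals <- ee$values
  if (any(vals < 0)) {
    if (!is.null(warn_label) && min(vals) < -1e-8 * max(abs(vals))) {
      inform(sprintf(
        "%s: clipped %d negative eigenvalue(s) (min %.3e) to 0 for factorization.",
        warn_label, sum(vals < 0), min(vals)
      ))
    }
    vals[vals < 0] <- 0
  }
  ee$vectors %*% (sqrt(vals) * t(ee$vectors))
}

# Project a symmetric matrix onto the PSD cone, clipping eigenvalues below
# -tol_frac * max(eigenvalue); returns the matrix and the raw minimum.
psd_clip <- function(S, tol_frac = 1e-8) {
  ee <- eigen(S, symmetric = TRUE)
  lmax <- max(ee$values)
  floor_val <- -tol_frac * abs(lmax)
  raw_min <- min(ee$values)
  vals <- pmax(ee$values, 0)
  out <- ee$vectors %*% (vals * t(ee$vectors))
  out <- (out + t(out)) / 2
  attr(out, "raw_min_eigenvalue") <- raw_min
  attr(out, "clipped") <- raw_min < floor_val
  out
}
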