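#' Define simulation ground truth
#'
#' Collects the generating parameters of a simulated trait: variance of each
#' random term, the inbreeding-depression regression coefficient, fixed
#' effect values, and the number of repeated records per animal. The
#' permanent environmental term requires repeated records; conversely a
#' single record per animal forces its variance to zero.
#'
#' @param additive,dominance,aa,ad,dd,pe,residual Term variances (trait
#'   units squared); `residual` must be positive.
#' @param inbreeding_depression_b Phenotype change per unit inbreeding
#'   coefficient (0 disables the covariate effect).
#' @param fixed_effect_values Named list: factor name -> named numeric vector
#'   of level effects.
#' @param records_per_animal Repeated records per animal (1 unless `pe > 0`).
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(additive = 0, dominance = 0, aa = 0, ad = 0,
                             dd = 0, pe = 0, residual = 1,
                             inbreeding_depression_b = 0,
                             fixed_effect_values = list(),
                             records_per_animal = 1L) {
  vars <- c(additive = additive, dominance = dominance, aa = aa, ad = ad,
            dd = dd, pe = pe, residual = residual)
  if (any(vars < 0)) abort("variances must be non-negative.")
  if (residual <= 0) abort("residual variance must be positive.")
  records_per_animal <- check_count(records_per_animal, "records_per_animal")
  if (pe > 0 && records_per_animal < 2L) {
    abort("permanent environmental variance requires repeated records.")
  }
  structure(list(variances = vars,
                 inbreeding_depression_b = inbreeding_depression_b,
                 fixed_effect_values = fixed_effect_values,
                 records_per_animal = records_per_animal),
            class = "simulation_truth")
}

#' Simulate SNP genotypes
#'
#' Two modes. `"hwe"` draws each call as Binomial(2, p_i), independently
#' across individuals and SNPs: an idealised unrelated sample in
#' Hardy-Weinberg proportions. `"gene_drop"` assigns two founder alleles per
#' SNP (Bernoulli(p_i)) and transmits one uniformly chosen parental allele
#' through every meiosis of the pedigree, so identity-by-descent — and hence
#' genomic inbreeding — tracks the pedigree.
#'
#' @param target Number of individuals (`hwe` mode) or a pedigree
#'   (`gene_drop` mode; also accepted for `hwe`, using its ids).
#' @param n_snps Number of SNPs.
#' @param freq_sampler Function of one integer returning allele frequencies
#'   in (0, 1); the default Uniform(0.05, 0.5) keeps all SNPs past common
#'   MAF filters.
#' @param mode `"hwe"` or `"gene_drop"`.
#' @param missing_rate Proportion of calls masked as missing.
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(target, n_snps,
                               freq_sampler = function(m) runif(m, 0.05, 0.5),
                               mode = c("hwe", "gene_drop"),
                               missing_rate = 0, seed = 1L) {
  mode <- match.arg(mode)
  n_snps <- check_count(n_snps, "n_snps")
  check_proportion(missing_rate, "missing_rate")
  is_ped <- inherits(target, "ped_tbl") || is.data.frame(target)
  if (mode == "gene_drop" && !is_ped) {
    abort("gene_drop mode requires a pedigree as `target`.")
  }
  with_seed(seed, {
    p <- freq_sampler(n_snps)
    if (any(p <= 0 | p >= 1)) {
      abort("freq_sampler must return frequencies strictly in (0, 1).")
    }
    if (mode == "hwe") {
      ids <- if (is_ped) as_pedigree(target)$id else paste0("ind", seq_len(target))
      n <- length(ids)
      calls <- matrix(rbinom(n * n_snps, 2L, rep(p, each = n)), n, n_snps)
    } else {
      ped <- as_pedigree(target)
      n <- nrow(ped)
      ids <- ped$id
      idx <- setNames(seq_len(n), ids)
      s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
      d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
      h1 <- matrix(0L, n, n_snps) # paternal haplotype
      h2 <- matrix(0L, n, n_snps) # maternal haplotype
      for (i in seq_len(n)) {
        h1[i, ] <- if (s[i] > 0L) {
          pick <- runif(n_snps) < 0.5
          ifelse(pick, h1[s[i], ], h2[s[i], ])
        } else rbinom(n_snps, 1L, p)
        h2[i, ] <- if (d[i] > 0L) {
          pick <- runif(n_snps) < 0.5
          ifelse(pick, h1[d[i], ], h2[d[i], ])
        } else rbinom(n_snps, 1L, p)
      }
      calls <- h1 + h2
    }
    if (missing_rate > 0) {
      calls[runif(length(calls)) < missing_rate] <- NA
    }
    genotype_matrix(calls, sample_ids = ids)
  })
}

#' Simulate phenotypes with additive, dominance and epistatic effects
#'
#' Builds the phenotype as y = X beta + f*b + a + d + e_aa + e_ad + e_dd +
#' pe + residual, expanded over repeated records. Each genetic vector is
#' drawn from a zero-mean multivariate normal whose covariance is the
#' corresponding genomic relationship matrix times its true variance,
#' using an eigenvalue-clipped symmetric factorisation (Hadamard-product
#' matrices are only numerically semidefinite). Effects are therefore
#' generated from the model's own covariance structures, so a fit of the
#' matching model is correctly specified — the clean surface for parameter
#' recovery.
#'
#' @param genotypes A [genotype_matrix()].
#' @param truth A [simulation_truth()].
#' @param pedigree Optional pedigree supplying inbreeding coefficients for
#'   the depression covariate; when absent and `b != 0`, genomic inbreeding
#'   from the additive matrix is used.
#' @param design Optional tibble of per-record factor levels with a column
#'   `animal`; defaults to `records_per_animal` records per genotyped
#'   animal with no factors.
#' @param grms Optional pre-built matrix list from [build_grms()] (saves
#'   recomputation across replicates).
#' @param seed Integer seed.
#' @return A list: `phenotypes` (tibble: `record`, `animal`, `y`, factor
#'   columns, `f`), `effects` (named list of true per-animal vectors),
#'   `truth`, and `grms` used.
#' @export
simulate_phenotypes <- function(genotypes, truth, pedigree = NULL,
                                design = NULL, grms = NULL, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(truth, "simulation_truth"))
  ids <- rownames(genotypes)
  n <- length(ids)
  vars <- truth$variances
  needed <- c(A = unname(vars["additive"] > 0), D = unname(vars["dominance"] > 0),
              AA = unname(vars["aa"] > 0), AD = unname(vars["ad"] > 0),
              DD = unname(vars["dd"] > 0))
  if (is.null(grms)) {
    kinds <- names(needed)[needed]
    grms <- if (length(kinds)) build_grms(genotypes, kinds = kinds) else list()
  }

  if (is.null(design)) {
    design <- tibble::tibble(animal = rep(ids, each = truth$records_per_animal))
  }
  if (!"animal" %in% names(design)) abort("`design` needs an `animal` column.")
  if (!all(design$animal %in% ids)) abort("design animals missing from genotypes.")

  f <- NULL
  if (truth$inbreeding_depression_b != 0) {
    f <- if (!is.null(pedigree)) pedigree_inbreeding(pedigree)
         else genomic_inbreeding(grms$additive %||% additive_grm(genotypes))
    if (!all(ids %in% f$id)) abort("inbreeding source does not cover all animals.")
  }

  with_seed(seed, {
    term_mat <- list(additive = "additive", dominance = "dominance",
                     aa = "aa", ad = "ad", dd = "dd")
    effects <- list()
    for (term in names(term_mat)) {
      if (vars[[term]] > 0) {
        G <- grms[[term_mat[[term]]]]
        L <- sym_factor(unclass(G), warn_label = paste0("simulate_phenotypes[", term, "]"))
        effects[[term]] <- setNames(drop(L %*% rnorm(n)) * sqrt(vars[[term]]), ids)
      }
    }
    if (vars[["pe"]] > 0) {
      effects$pe <- setNames(rnorm(n, sd = sqrt(vars[["pe"]])), ids)
    }

    N <- nrow(design)
    y <- rnorm(N, sd = sqrt(vars[["residual"]]))
    for (term in names(effects)) y <- y + effects[[term]][design$animal]
    fe_applied <- list()
    for (fac in names(truth$fixed_effect_values)) {
      if (!fac %in% names(design)) {
        abort(sprintf("fixed factor '%s' missing from design.", fac))
      }
      lev <- truth$fixed_effect_values[[fac]]
      y <- y + unname(lev[as.character(design[[fac]])])
      fe_applied[[fac]] <- lev
    }
    fvec <- rep(0, N)
    if (!is.null(f)) {
      fvec <- f$F[match(design$animal, f$id)]
      y <- y + truth$inbreeding_depression_b * fvec
    }
    pheno <- dplyr::bind_cols(
      tibble::tibble(record = seq_len(N), animal = design$animal),
      design[setdiff(names(design), "animal")],
      tibble::tibble(y = unname(y), f = fvec)
    )
    list(phenotypes = pheno, effects = effects, truth = truth, grms = grms)
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the genotype TSV, pedigree CSV (empty parent = unknown), phenotype
#' TSV and a YAML-like truth file echoing the generating parameters.
#'
#' @param sim Result of [simulate_phenotypes()].
#' @param genotypes The [genotype_matrix()] used.
#' @param dir Output directory (created if needed).
#' @param pedigree Optional pedigree to write alongside.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, genotypes, dir, pedigree = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(genotypes, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(sim$phenotypes, file.path(dir, "phenotypes.tsv"),
                   progress = FALSE)
  if (!is.null(pedigree)) {
    ped <- as_pedigree(pedigree)
    ped$sire[is.na(ped$sire)] <- ""
    ped$dam[is.na(ped$dam)] <- ""
    readr::write_csv(ped[c("id", "sire", "dam")], file.path(dir, "pedigree.csv"),
                     progress = FALSE)
  }
  tv <- sim$truth$variances
  lines <- c(paste0(names(tv), ": ", unname(tv)),
             paste0("inbreeding_depression_b: ", sim$truth$inbreeding_depression_b),
             paste0("records_per_animal: ", sim$truth$records_per_animal))
  writeLines(lines, file.path(dir, "truth.txt"))
  invisible(dir)
}
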