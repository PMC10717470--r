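#' Configure an end-to-end analysis run
#'
#' Validates and normalises the configuration consumed by
#' [run_pipeline()]: either input file paths (`genotype_file`,
#' `phenotype_file`, optional `pedigree_file`) or a `simulate` block with
#' the generator parameters; QC thresholds; the list of catalogue models to
#' fit; the inbreeding source; and cross-validation settings.
#'
#' @param models Character vector of catalogue model names.
#' @param out_dir Output directory for reports.
#' @param simulate `NULL`, or a list with `n_animals` (or `pedigree`
#'   parameters), `n_snps`, `truth` (a [simulation_truth()]) and `seed`.
#' @param genotype_file,phenotype_file,pedigree_file Input paths
#'   (alternative to `simulate`).
#' @param qc List of [apply_qc()] thresholds, or `NULL` to skip QC.
#' @param inbreeding_source `"pedigree"` or `"genomic"`.
#' @param cv `NULL`, or list with fold count `k`, `seed`, and `model` (the
#'   model to validate; default first of `models`).
#' @param seed Master seed for all stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(models, out_dir, simulate = NULL,
                       genotype_file = NULL, phenotype_file = NULL,
                       pedigree_file = NULL,
                       qc = list(snp_call_rate_min = 0.9, maf_min = 0.01,
                                 hwe_p_min = 1e-5),
                       inbreeding_source = c("genomic", "pedigree"),
                       cv = NULL, seed = 1L) {
  inbreeding_source <- match.arg(inbreeding_source)
  known <- names(model_catalogue())
  if (!all(models %in% known)) {
    abort(sprintf("unknown model name(s): %s",
                  paste(setdiff(models, known), collapse = ", ")))
  }
  if (is.null(simulate) && (is.null(genotype_file) || is.null(phenotype_file))) {
    abort("supply either a `simulate` block or genotype and phenotype files.")
  }
  if (inbreeding_source == "pedigree" && is.null(pedigree_file) &&
      is.null(simulate)) {
    abort("pedigree inbreeding requires a pedigree file.")
  }
  structure(list(models = models, out_dir = out_dir, simulate = simulate,
                 genotype_file = genotype_file,
                 phenotype_file = phenotype_file,
                 pedigree_file = pedigree_file, qc = qc,
                 inbreeding_source = inbreeding_source, cv = cv,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate-or-load, genotype QC, relationship-matrix
#' construction, the model battery of REML fits, variance ratios, LR
#' cross-validation (optional) and the model-comparison report. Every
#' stochastic stage draws its seed from the config's master seed, so a
#' rerun with the same config reproduces every number. Non-converged
#' models are reported and flagged; the pipeline continues.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the fitted objects and report tibbles;
#'   reports are also written as TSV under `cfg$out_dir` together with a
#'   JSON run manifest and a line-oriented log.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- character()
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    log_lines <<- c(log_lines, line)
  }
  seeds <- derive_seeds(cfg$seed, 4L)

  # ---- inputs -------------------------------------------------------------
  ped <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    say("simulate", sprintf("generating %d animals x %d SNPs",
                            sim$n_animals %||% NA, sim$n_snps))
    if (!is.null(sim$pedigree)) {
      ped <- sim$pedigree
      geno <- simulate_genotypes(ped, sim$n_snps, mode = "gene_drop",
                                 seed = seeds[1])
    } else {
      geno <- simulate_genotypes(sim$n_animals, sim$n_snps, mode = "hwe",
                                 seed = seeds[1])
    }
    simres <- simulate_phenotypes(geno, sim$truth, pedigree = ped,
                                  seed = seeds[2])
    pheno <- simres$phenotypes
  } else {
    say("load", cfg$genotype_file)
    geno <- read_genotypes(cfg$genotype_file,
                           dialect = cfg$genotype_dialect %||% "tsv")
    pheno <- readr::read_tsv(cfg$phenotype_file, show_col_types = FALSE,
                             progress = FALSE)
    if (!is.null(cfg$pedigree_file)) {
      ped <- as_pedigree(readr::read_csv(cfg$pedigree_file,
                                         show_col_types = FALSE,
                                         progress = FALSE))
    }
  }

  # ---- QC -----------------------------------------------------------------
  if (!is.null(cfg$qc)) {
    qc <- do.call(apply_qc, c(list(geno), cfg$qc))
    geno <- qc$genotypes
    say("qc", sprintf("%d SNPs and %d individuals retained",
                      ncol(geno), nrow(geno)))
    readr::write_tsv(qc$report, file.path(cfg$out_dir, "qc_report.tsv"),
                     progress = FALSE)
  }

  # ---- matrices -----------------------------------------------------------
  terms_needed <- unique(unlist(lapply(cfg$models,
                                       function(m) model_catalogue()[[m]]$random)))
  kind_map <- c(additive = "A", dominance = "D", aa = "AA", ad = "AD", dd = "DD")
  kinds <- unname(kind_map[intersect(names(kind_map), terms_needed)])
  grms <- build_grms(geno, kinds = kinds)
  say("grm", paste("built:", paste(names(grms), collapse = ", ")))

  inb <- NULL
  if (any(vapply(cfg$models, function(m) model_catalogue()[[m]]$inbreeding,
                 TRUE))) {
    inb <- if (cfg$inbreeding_source == "pedigree") {
      if (is.null(ped)) abort("pedigree inbreeding requested but no pedigree available.")
      pedigree_inbreeding(ped)
    } else {
      genomic_inbreeding(grms$additive %||% additive_grm(geno))
    }
  }

  # ---- model battery ------------------------------------------------------
  fits <- list()
  ratio_rows <- list()
  for (m in cfg$models) {
    spec <- model_spec(m)
    ds <- build_design(pheno, spec, grms,
                       inbreeding = if (spec$inbreeding) inb)
    fit <- fit_reml(ds)
    fits[[m]] <- fit
    say("fit", sprintf("%s: logL %.4f (%s)", m, fit$reml_loglik,
                       if (fit$converged) "converged" else "NOT converged"))
    ratio_rows[[m]] <- dplyr::mutate(variance_ratios(fit), model = m,
                                     .before = 1L)
  }
  variance_table <- dplyr::bind_rows(lapply(fits, tidy))
  ratio_table <- dplyr::bind_rows(ratio_rows)
  readr::write_tsv(variance_table,
                   file.path(cfg$out_dir, "variance_components.tsv"),
                   progress = FALSE)
  readr::write_tsv(ratio_table, file.path(cfg$out_dir, "variance_ratios.tsv"),
                   progress = FALSE)

  # ---- validation ---------------------------------------------------------
  validation <- NULL
  if (!is.null(cfg$cv)) {
    vmodel <- cfg$cv$model %||% cfg$models[1]
    spec <- model_spec(vmodel)
    folds <- make_folds(unique(pheno$animal), k = cfg$cv$k %||% 10L,
                        seed = cfg$cv$seed %||% seeds[3])
    validation <- cross_validate(pheno, spec, grms,
                                 inbreeding = if (spec$inbreeding) inb,
                                 folds = folds)
    say("validate", sprintf("%s: accuracy %.4f", vmodel,
                            validation$aggregate$accuracy))
    readr::write_tsv(tidy(validation),
                     file.path(cfg$out_dir, "lr_validation.tsv"),
                     progress = FALSE)
  }

  # ---- comparison ---------------------------------------------------------
  report <- NULL
  if (length(fits) > 1L) {
    report <- comparison_report(fits, reference = cfg$models[1])
    readr::write_tsv(report$aic_table, file.path(cfg$out_dir, "aic_table.tsv"),
                     progress = FALSE)
    if (nrow(report$lrt_entries)) {
      readr::write_tsv(report$lrt_entries, file.path(cfg$out_dir, "lrt.tsv"),
                       progress = FALSE)
    }
    readr::write_tsv(report$spearman, file.path(cfg$out_dir, "spearman.tsv"),
                     progress = FALSE)
    readr::write_tsv(report$overlap, file.path(cfg$out_dir, "top_overlap.tsv"),
                     progress = FALSE)
    say("compare", sprintf("reference %s over %d models", cfg$models[1],
                           length(fits)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("epigblup")),
    master_seed = cfg$seed,
    stage_seeds = as.list(setNames(seeds, c("genotypes", "phenotypes",
                                            "folds", "reserve"))),
    models = cfg$models,
    inbreeding_source = cfg$inbreeding_source,
    n_individuals = nrow(geno), n_snps = ncol(geno),
    config_hash = rlang::hash(cfg)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(genotypes = geno, phenotypes = pheno, grms = grms,
                 fits = fits, variance_table = variance_table,
                 ratio_table = ratio_table, validation = validation,
                 report = report, manifest = manifest))
}
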