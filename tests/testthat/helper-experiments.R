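# Replicated simulation experiments shared by the acceptance-level tests.
# Samples are gene-dropped through a two-generation random-mating pedigree:
# livestock-style family structure is what separates Hadamard-product
# epistatic covariances from the residual (for unrelated individuals G_AA
# is numerically close to the identity) and what gives masked animals
# informative genomic ties to the training set.

family_sample <- function(n_founders, m, seed) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 2))
  ped <- simulate_pedigree(n_founders, 2,
                           matings_per_generation = n_founders,
                           offspring_per_mating = 2, seed = seeds[1])
  geno <- sim_poly_geno(ped, m, mode = "gene_drop", seed = seeds[2])
  list(ped = ped, geno = geno)
}

# One parameter-recovery replicate: simulate additive + dominance + aa
# truth, fit the matching model (MADE1) and the additive-only model (MA).
recovery_replicate <- function(r, seed0, truth) {
  seeds <- withr::with_seed(seed0 + r, sample.int(.Machine$integer.max, 2))
  fam <- family_sample(100, 2000, seed = seeds[1])
  grms <- build_grms(fam$geno, kinds = c("A", "D", "AA"))
  sim <- simulate_phenotypes(fam$geno, truth, grms = grms, seed = seeds[2])
  f_full <- fit_reml(build_design(sim$phenotypes, model_spec("MADE1"), grms))
  f_ma <- fit_reml(build_design(sim$phenotypes, model_spec("MA"), grms))
  c(setNames(f_full$variances$estimate, f_full$variances$term),
    ma_additive = f_ma$variances$estimate[f_ma$variances$term == "additive"],
    converged = as.numeric(f_full$converged && f_ma$converged))
}

# One LR-method calibration replicate on correctly specified additive data.
lr_replicate <- function(r, seed0, h2 = 0.3, k = 10) {
  seeds <- withr::with_seed(seed0 + r, sample.int(.Machine$integer.max, 3))
  fam <- family_sample(50, 400, seed = seeds[1])
  truth <- simulation_truth(additive = h2, residual = 1 - h2)
  sim <- simulate_phenotypes(fam$geno, truth, seed = seeds[2])
  folds <- make_folds(rownames(fam$geno), k = k, seed = seeds[3])
  cv <- cross_validate(sim$phenotypes, model_spec("MA"), sim$grms,
                       folds = folds)
  unlist(cv$aggregate[c("bias", "dispersion", "accuracy")])
}

# One null-hypothesis LRT replicate: data carry no dominance variance; the
# test compares MA (reduced) with MAD (complete).
null_lrt_replicate <- function(r, seed0) {
  seeds <- withr::with_seed(seed0 + r, sample.int(.Machine$integer.max, 2))
  fam <- family_sample(40, 250, seed = seeds[1])
  truth <- simulation_truth(additive = 0.3, residual = 0.7)
  grms <- build_grms(fam$geno, kinds = c("A", "D"))
  sim <- simulate_phenotypes(fam$geno, truth, grms = grms, seed = seeds[2])
  f0 <- fit_reml(build_design(sim$phenotypes, model_spec("MA"), grms))
  f1 <- fit_reml(build_design(sim$phenotypes, model_spec("MAD"), grms))
  suppressMessages(likelihood_ratio_test(f0, f1)$p_value)
}
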