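test_that("HWE genotypes recover the target allele frequency", {
  g <- simulate_genotypes(100, 1, freq_sampler = function(m) rep(0.5, m),
                          seed = 1)
  p_hat <- sum(g) / (2 * 100)
  # 99.9% binomial CI around 0.5 with 200 draws
  expect_lt(abs(p_hat - 0.5), 3.3 * sqrt(0.25 / 200))
})

test_that("missing_rate = 0 gives complete data; same seed is bit-identical", {
  g1 <- simulate_genotypes(50, 100, seed = 2)
  expect_false(anyNA(g1))
  g2 <- simulate_genotypes(50, 100, seed = 2)
  expect_identical(g1, g2)
  g3 <- simulate_genotypes(50, 100, missing_rate = 0.1, seed = 3)
  expect_gt(mean(is.na(g3)), 0.05)
})

test_that("seeds drawn from the caller's stream advance it", {
  # seed arguments are often passed as fresh draws from the session RNG;
  # the internal state restore must not roll those draws back
  withr::with_seed(99, {
    g1 <- simulate_genotypes(10, 20, seed = sample.int(1e6, 1))
    g2 <- simulate_genotypes(10, 20, seed = sample.int(1e6, 1))
  })
  expect_false(identical(unclass(g1), unclass(g2)))
})

test_that("gene-dropped genotypes reflect pedigree inbreeding in G_A diagonals", {
  ped <- simulate_pedigree(40, 3, matings_per_generation = 20,
                           offspring_per_mating = 2,
                           full_sib_mating_fraction = 0.6, seed = 13)
  geno <- sim_poly_geno(ped, 5000, mode = "gene_drop", seed = 14)
  Fp <- pedigree_inbreeding(ped)
  diag_excess <- diag(additive_grm(geno)) - 1
  expect_gt(cor(Fp$F, diag_excess), 0.3)
})

test_that("gene-dropped founders stay near Hardy-Weinberg proportions", {
  ped <- simulate_pedigree(300, 0, seed = 15)
  geno <- simulate_genotypes(ped, 400, mode = "gene_drop", seed = 16)
  pvals <- apply(unclass(geno), 2, function(x) {
    hwe_chi_square(sum(x == 2), sum(x == 1), sum(x == 0))$p_value
  })
  # nominal non-rejection: about 5% of SNPs below 0.05 (binomial slack)
  expect_lt(mean(pvals < 0.05), 0.10)
})

test_that("pure-noise truth gives unit phenotypic variance", {
  geno <- simulate_genotypes(2000, 10, seed = 17)
  truth <- simulation_truth(residual = 1)
  sim <- simulate_phenotypes(geno, truth, seed = 18)
  expect_equal(var(sim$phenotypes$y), 1, tolerance = 0.1)
  expect_length(sim$effects, 0)
})

test_that("repeated records give the repeatability correlation structure", {
  geno <- simulate_genotypes(150, 600, seed = 19)
  truth <- simulation_truth(additive = 0.25, pe = 0.35, residual = 0.4,
                            records_per_animal = 15L)
  sim <- simulate_phenotypes(geno, truth, seed = 20)
  ph <- sim$phenotypes
  # within-animal correlation ~ (s2_a + s2_pe) / total = 0.6
  wide <- tapply(ph$y, ph$animal, function(v) v)
  animal_mean <- tapply(ph$y, ph$animal, mean)
  v_between <- var(animal_mean)
  v_total <- var(ph$y)
  # intraclass correlation via ANOVA decomposition
  ms_within <- mean(tapply(ph$y, ph$animal, var))
  icc <- 1 - ms_within / v_total
  expect_equal(icc, 0.6, tolerance = 0.1)
})

test_that("inbreeding depression shifts inbred animals by b * F", {
  ped <- simulate_pedigree(60, 2, matings_per_generation = 30,
                           offspring_per_mating = 2,
                           full_sib_mating_fraction = 0.5, seed = 23)
  geno <- sim_poly_geno(ped, 300, mode = "gene_drop", seed = 24)
  truth <- simulation_truth(residual = 0.05, inbreeding_depression_b = -2)
  sim <- simulate_phenotypes(geno, truth, pedigree = ped, seed = 25)
  ph <- sim$phenotypes
  grp0 <- ph$y[ph$f == 0]
  grp25 <- ph$y[abs(ph$f - 0.25) < 1e-9]
  expect_gt(length(grp25), 3)
  expect_equal(mean(grp25) - mean(grp0), -0.5, tolerance = 0.15)
})

test_that("simulated effect variances converge to truth at large n", {
  geno <- simulate_genotypes(2000, 800, seed = 26)
  truth <- simulation_truth(additive = 0.5, residual = 0.5)
  sim <- simulate_phenotypes(geno, truth, seed = 27)
  a <- sim$effects$additive
  G <- unclass(sim$grms$additive)
  # a ~ N(0, G * s2): the GLS quadratic form a' Ginv a / n estimates s2
  ee <- eigen(G, symmetric = TRUE)
  pos <- ee$values > 1e-8
  w <- crossprod(ee$vectors[, pos], a)
  s2_hat <- sum(w^2 / ee$values[pos]) / sum(pos)
  se <- truth$variances["additive"] * sqrt(2 / sum(pos))
  expect_lt(abs(s2_hat - 0.5), 3 * se)
})

test_that("fixed effect values enter the phenotype mean", {
  geno <- simulate_genotypes(400, 10, seed = 28)
  truth <- simulation_truth(residual = 0.01,
                            fixed_effect_values = list(
                              batch = c(b1 = 0, b2 = 5)))
  design <- tibble::tibble(animal = rownames(geno),
                           batch = rep(c("b1", "b2"), 200))
  sim <- simulate_phenotypes(geno, truth, design = design, seed = 29)
  ph <- sim$phenotypes
  expect_equal(mean(ph$y[ph$batch == "b2"]) - mean(ph$y[ph$batch == "b1"]),
               5, tolerance = 0.1)
})

test_that("simulation files round-trip as plain text", {
  dir <- withr::local_tempdir()
  ped <- simulate_pedigree(10, 1, matings_per_generation = 5, seed = 30)
  geno <- sim_poly_geno(ped, 60, mode = "gene_drop", seed = 31)
  truth <- simulation_truth(additive = 0.3, residual = 0.7)
  sim <- simulate_phenotypes(geno, truth, seed = 32)
  write_simulation(sim, geno, dir, pedigree = ped)
  expect_true(all(file.exists(file.path(dir, c("genotypes.tsv",
                                               "phenotypes.tsv",
                                               "pedigree.csv", "truth.txt")))))
  g2 <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_identical(unclass(g2), unclass(geno))
  ped2 <- as_pedigree(readr::read_csv(file.path(dir, "pedigree.csv"),
                                      show_col_types = FALSE))
  expect_equal(ped2$id, ped$id)
})
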