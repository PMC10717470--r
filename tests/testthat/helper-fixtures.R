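# Shared fixture builders; everything is generated in code at test time.

# 3-animal, 1-SNP matrix whose relationship matrices are known by hand.
toy_genotypes <- function() {
  genotype_matrix(matrix(c(2L, 1L, 0L), 3, 1),
                  sample_ids = c("a", "b", "c"), snp_ids = "s1")
}

# Simulate genotypes and drop SNPs that came out monomorphic in-sample
# (tiny samples fix low-frequency alleles often; GRMs need polymorphism).
sim_poly_geno <- function(target, m, seed, mode = "hwe", ...) {
  g <- simulate_genotypes(target, m, mode = mode, seed = seed, ...)
  p <- colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
  genotype_matrix(unclass(g)[, p > 0 & p < 1, drop = FALSE])
}

# Strip grm attributes for plain-matrix comparisons.
bare <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x
}

# Quick correctly specified additive simulation for REML/LR tests.
quick_sim <- function(n = 150, m = 400, h2 = 0.3, seed = 1,
                      records_per_animal = 1L, pe = 0) {
  seeds <- withr::with_seed(seed, sample.int(1e6, 2))
  geno <- sim_poly_geno(n, m, seed = seeds[1])
  truth <- simulation_truth(additive = h2, residual = 1 - h2 - pe, pe = pe,
                            records_per_animal = records_per_animal)
  sim <- simulate_phenotypes(geno, truth, seed = seeds[2])
  c(sim, list(genotypes = geno))
}

# Phenotype table with multi-level factors for design-building tests.
factorial_phenotypes <- function(n = 24, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      animal = paste0("ind", rep(seq_len(n / 2), each = 2)),
      week = sample(c("w1", "w2"), n, replace = TRUE),
      day = sample(c("d1", "d2", "d3"), n, replace = TRUE),
      parity = sample(c("p1", "p2"), n, replace = TRUE),
      temp = rnorm(n, 22, 3),
      y = rnorm(n)
    )
  })
}
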