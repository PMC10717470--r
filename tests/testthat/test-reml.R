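# Dense-formula oracle for the restricted log-likelihood, written
# independently of the package's evaluation path.
oracle_loglik <- function(y, X, V) {
  Vinv <- solve(V)
  XtVX <- t(X) %*% Vinv %*% X
  P <- Vinv - Vinv %*% X %*% solve(XtVX) %*% t(X) %*% Vinv
  -0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
            drop(t(y) %*% P %*% y))
}

make_ds <- function(n = 30, m = 120, h2 = 0.4, seed = 1, spec = model_spec("MA")) {
  sim <- quick_sim(n = n, m = m, h2 = h2, seed = seed)
  inb <- if (spec$inbreeding) genomic_inbreeding(sim$grms$additive)
  build_design(sim$phenotypes, spec, sim$grms, inbreeding = inb)
}

test_that("restricted log-likelihood matches a dense-formula oracle", {
  ds <- make_ds(n = 25, seed = 2)
  for (th in list(c(additive = 0.2, residual = 0.8),
                  c(additive = 1.3, residual = 0.1),
                  c(additive = 1e-6, residual = 1))) {
    V <- th["additive"] * ds$Z %*% unclass(ds$G$additive) %*% t(ds$Z) +
      th["residual"] * diag(ds$n_records)
    expect_equal(reml_loglikelihood(ds, th),
                 as.numeric(oracle_loglik(ds$y, ds$X, V)), tolerance = 1e-8)
  }
})

test_that("REML likelihood is invariant to translating y (intercept present)", {
  ds <- make_ds(n = 20, seed = 3)
  th <- c(additive = 0.3, residual = 0.7)
  ll <- reml_loglikelihood(ds, th)
  ds2 <- ds
  ds2$y <- ds$y + 17.5
  expect_equal(reml_loglikelihood(ds2, th), ll, tolerance = 1e-8)
})

test_that("scaling y by c and variances by c^2 shifts logL by -(n-p) log c", {
  ds <- make_ds(n = 20, seed = 4)
  th <- c(additive = 0.3, residual = 0.7)
  ll <- reml_loglikelihood(ds, th)
  cc <- 2.5
  ds2 <- ds
  ds2$y <- cc * ds$y
  ll2 <- reml_loglikelihood(ds2, cc^2 * th)
  expect_equal(ll2 - ll, -(ds$n_records - ncol(ds$X)) * log(cc),
               tolerance = 1e-8)
})

test_that("AI-REML matches derivative-free maximization on 2-component toys", {
  for (seed in c(5, 6, 7)) {
    ds <- make_ds(n = 30, seed = seed)
    fit <- fit_reml(ds)
    ref <- optim(c(0.3, 0.5),
                 function(th) -reml_loglikelihood(
                   ds, setNames(th, c("additive", "residual"))),
                 method = "L-BFGS-B", lower = 1e-8,
                 control = list(factr = 1e3))
    expect_true(fit$converged)
    expect_equal(fit$variances$estimate, ref$par, tolerance = 1e-4)
    expect_gte(fit$reml_loglik, -ref$value - 1e-6)
  }
})

test_that("null additive components are pinned at the boundary when the
           optimum is negative, and match the oracle otherwise", {
  n_pinned <- 0L
  for (s in 1:4) {
    g <- sim_poly_geno(100, 300, seed = 8 + 10 * s)
    sim <- simulate_phenotypes(g, simulation_truth(residual = 1),
                               seed = 9 + 10 * s)
    grms <- build_grms(g, kinds = "A")
    ds <- build_design(sim$phenotypes, model_spec("MA"), grms)
    fit <- fit_reml(ds)
    expect_true(fit$converged)
    a <- fit$variances[fit$variances$term == "additive", ]
    if (a$at_boundary) {
      n_pinned <- n_pinned + 1L
      # pinned estimates print at the ~1e-8 x phenotypic-variance scale
      expect_lt(a$estimate, 1e-6)
      expect_equal(a$estimate, fit$boundary)
    } else {
      ref <- optim(c(0.2, 0.8),
                   function(th) -reml_loglikelihood(
                     ds, setNames(th, c("additive", "residual"))),
                   method = "L-BFGS-B", lower = 1e-9,
                   control = list(factr = 1e3))
      expect_equal(fit$variances$estimate, ref$par, tolerance = 1e-3)
    }
  }
  # under the null about half the replicates sit at the boundary
  expect_gte(n_pinned, 1L)
})

test_that("fits are invariant to record order and factor relabeling", {
  sim <- quick_sim(n = 60, m = 200, seed = 10)
  pt <- sim$phenotypes
  pt$grp <- rep(c("g1", "g2", "g3"), length.out = nrow(pt))
  spec <- model_spec("MA", fixed = list("grp"))
  f1 <- fit_reml(build_design(pt, spec, sim$grms))
  perm <- withr::with_seed(11, sample(nrow(pt)))
  f2 <- fit_reml(build_design(pt[perm, ], spec, sim$grms))
  pt3 <- pt
  pt3$grp <- c(g1 = "zzz", g2 = "aaa", g3 = "mmm")[pt$grp]
  f3 <- fit_reml(build_design(pt3, spec, sim$grms))
  expect_equal(f1$reml_loglik, f2$reml_loglik, tolerance = 1e-8)
  expect_equal(f1$reml_loglik, f3$reml_loglik, tolerance = 1e-8)
})

test_that("converged fits have usable curvature and stable solutions", {
  ds <- make_ds(n = 50, m = 200, seed = 12)
  fit <- fit_reml(ds)
  expect_true(fit$converged)
  expect_true(all(fit$variances$std_error > 0))
  # GEBVs exist for every animal, including via the mixed-model identities
  expect_length(gebv(fit), ds$n_animals)
  expect_equal(names(gebv(fit)), ds$animal_ids)
})

test_that("GEBV accuracy increases with true heritability", {
  cors <- sapply(c(0.1, 0.6), function(h2) {
    mean(sapply(1:5, function(r) {
      sim <- quick_sim(n = 100, m = 300, h2 = h2, seed = 100 * h2 + r)
      ds <- build_design(sim$phenotypes, model_spec("MA"), sim$grms)
      fit <- fit_reml(ds)
      cor(gebv(fit), sim$effects$additive[names(gebv(fit))])
    }))
  })
  expect_gt(cors[2], cors[1])
})

test_that("repeatability model separates pe from residual", {
  sim <- quick_sim(n = 80, m = 300, h2 = 0.3, pe = 0.3, seed = 13,
                   records_per_animal = 8L)
  inb <- genomic_inbreeding(sim$grms$additive)
  ds <- build_design(sim$phenotypes, model_spec("MAIpe"), sim$grms,
                     inbreeding = inb)
  fit <- fit_reml(ds)
  expect_true(fit$converged)
  est <- setNames(fit$variances$estimate, fit$variances$term)
  expect_lt(abs(est["pe"] - 0.3), 0.15)
  expect_lt(abs(est["residual"] - 0.4), 0.05)
})

test_that("variance ratios reproduce printed-component arithmetic", {
  # single-trait worked example: components in trait units
  vr <- variance_ratios(c(additive = 1310.62, residual = 2190.12))
  expect_equal(round(vr$ratio[vr$term == "additive"], 4), 0.3744)
  # repeatability example with epistasis: phenotypic and total-genetic scales
  comp <- c(additive = 0.0298, aa = 0.1379, pe = 0.0137, residual = 0.8463)
  vr_p <- variance_ratios(comp)
  expect_equal(round(vr_p$ratio[vr_p$term == "aa"], 4), 0.1342)
  vr_g <- variance_ratios(comp, denominator = "total_genetic")
  expect_equal(vr_g$ratio[vr_g$term == "aa"], 0.8222, tolerance = 2e-4)
  # degenerate zero-additive edge
  vr0 <- variance_ratios(c(additive = 0, residual = 1))
  expect_equal(vr0$ratio, 0)
})

test_that("delta-method ratio SEs agree with a Monte-Carlo oracle", {
  ds <- make_ds(n = 60, m = 200, seed = 14)
  fit <- fit_reml(ds)
  vr <- variance_ratios(fit)
  est <- fit$variances$estimate
  vc <- fit$vcov
  draws <- withr::with_seed(15, MASS::mvrnorm(20000, est, vc))
  mc <- apply(draws, 1, function(th) th[1] / sum(th))
  # the MC oracle itself linearises only approximately; 10% agreement
  expect_equal(vr$std_error[1], sd(mc), tolerance = 0.1)
})

test_that("model AIC follows -2 logL + 2t and nesting monotonicity", {
  fake <- structure(list(reml_loglik = -100, n_params = 2), class = "reml_fit")
  expect_equal(model_aic(fake), 204)
  sim <- quick_sim(n = 80, m = 300, h2 = 0.3, seed = 16)
  sim$grms <- c(sim$grms, build_grms(sim$genotypes, kinds = c("D", "AA")))
  ds_ma <- build_design(sim$phenotypes, model_spec("MA"), sim$grms)
  ds_full <- build_design(sim$phenotypes, model_spec("MADE1"), sim$grms)
  f_ma <- fit_reml(ds_ma)
  f_full <- fit_reml(ds_full)
  # complete model attains at least the reduced model's likelihood
  expect_gte(f_full$reml_loglik, f_ma$reml_loglik - 1e-6)
  # null extra terms: logL ~ unchanged, AIC up by ~2 per extra parameter
  expect_lt(f_full$reml_loglik - f_ma$reml_loglik, 2)
})

test_that("tidy and glance return broom-shaped tibbles", {
  ds <- make_ds(n = 30, seed = 17)
  fit <- fit_reml(ds)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("model", "term", "estimate", "std_error", "at_boundary"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$aic, model_aic(fit))
  tf <- tidy(fit, effects = "fixed")
  expect_true("(Intercept)" %in% tf$term)
})
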