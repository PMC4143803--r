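# Replicate simulator: spectrum, moments, reproducibility, recovery.

test_that("the MAF spectrum is rare-skewed and matches its distribution", {
  set.seed(61)
  sp <- list(shape1 = 0.2, shape2 = 5, max = 0.5)
  maf <- rpls:::draw_maf_spectrum(1e4, sp)
  # majority of variants are rare (direct integration of the Beta cdf
  # puts > 50% of mass below maf 0.05)
  expect_gt(pbeta(0.05, 0.2, 5), 0.5)
  expect_gt(mean(maf < 0.05), 0.5)
  # KS agreement with the configured Beta (truncation mass at 0.5 is
  # negligible for this shape)
  ks <- suppressWarnings(ks.test(maf, function(x) pbeta(x, 0.2, 5)))
  expect_gt(ks$p.value, 0.01)
})

test_that("dosages follow binomial HWE moments", {
  sc <- simulation_config(list(gene_spec("G", 1, causal_idx = 1L,
                                         effect_sizes = 0,
                                         causal_maf = 0.5)),
                          n_samples = 4000L, n_replicates = 1L, seed = 62)
  G <- simulate_genotypes(sc)
  x <- G$dosages[, 1]
  expect_equal(mean(x), 1.0, tolerance = 0.07)
  expect_equal(var(x), 0.5, tolerance = 0.07)
})

test_that("within-gene LD is off by default and induced by the copula", {
  mk <- function(rho, seed) {
    sc <- simulation_config(list(gene_spec("G", 12L, causal_idx = 1:12,
                                           effect_sizes = rep(0, 12),
                                           causal_maf = rep(0.3, 12))),
                            n_samples = 800L, n_replicates = 1L,
                            ld_rho = rho, seed = seed)
    cor(simulate_genotypes(sc)$dosages)
  }
  c0 <- mk(0, 63)
  off0 <- c0[upper.tri(c0)]
  expect_lt(abs(mean(off0)), 0.02)
  c7 <- mk(0.7, 63)
  adj7 <- c7[cbind(1:11, 2:12)]
  expect_gt(mean(adj7), 0.3)
})

test_that("the same seed reproduces the replicate set exactly", {
  sc <- default_scenario(seed = 64, n_samples = 40L, n_replicates = 3L)
  sc$genes <- sc$genes[1:5]
  r1 <- simulate_phenotypes(simulate_genotypes(sc), sc)
  r2 <- simulate_phenotypes(simulate_genotypes(sc), sc)
  expect_identical(r1$phenotypes, r2$phenotypes)
  expect_identical(r1$genotype$dosages, r2$genotype$dosages)
  sc2 <- sc; sc2$seed <- 65L
  r3 <- simulate_phenotypes(simulate_genotypes(sc2), sc2)
  expect_false(identical(r1$phenotypes, r3$phenotypes))
})

test_that("regression on the true causal set recovers the signed effects", {
  sc <- simulation_config(
    list(gene_spec("G", 6L, causal_idx = c(2L, 5L),
                   effect_sizes = c(0.5, -0.4),
                   causal_maf = c(0.3, 0.2))),
    n_samples = 1000L, n_replicates = 5L, seed = 66)
  G <- simulate_genotypes(sc)
  rs <- simulate_phenotypes(G, sc)
  for (r in 1:5) {
    fit <- summary(lm(rs$phenotypes[, r] ~ G$dosages[, c(2, 5)] +
                        rs$covariates))
    est <- fit$coefficients[2:3, 1]
    se <- fit$coefficients[2:3, 2]
    expect_true(all(abs(est - c(0.5, -0.4)) < 2.5 * se))
  }
})

test_that("the liability threshold yields the configured prevalence", {
  sc <- simulation_config(list(gene_spec("G", 5L)),
                          n_samples = 500L, n_replicates = 50L,
                          trait_model = "liability", prevalence = 0.3,
                          seed = 67)
  rs <- simulate_phenotypes(simulate_genotypes(sc), sc)
  expect_true(all(rs$phenotypes %in% 0:1))
  expect_equal(mean(rs$phenotypes), 0.3, tolerance = 0.03)
})

test_that("the hypertension trait model dichotomizes pressure plus medication", {
  sc <- simulation_config(list(gene_spec("G", 5L)),
                          n_samples = 300L, n_replicates = 4L,
                          trait_model = "htn", seed = 68)
  rs <- simulate_phenotypes(simulate_genotypes(sc), sc)
  expect_true(all(rs$phenotypes %in% 0:1))
  # everyone on medication is a case in every replicate
  med <- rs$medication == 1
  expect_true(all(rs$phenotypes[med, ] == 1))
  # case rule consistent with derive_htn on the stored pressures
  r <- 2
  expect_equal(rs$phenotypes[, r],
               derive_htn(rs$sbp[, r], rs$dbp[, r], rs$medication),
               ignore_attr = TRUE)
})

test_that("scenario configurations round-trip through JSON", {
  sc <- default_scenario(seed = 69, n_samples = 30L, n_replicates = 2L)
  f <- tempfile(fileext = ".json")
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  expect_equal(sc2$n_samples, sc$n_samples)
  expect_equal(length(sc2$genes), length(sc$genes))
  expect_equal(sc2$genes[[1]]$effect_sizes, sc$genes[[1]]$effect_sizes)
  # identical draws from the round-tripped configuration
  expect_identical(simulate_genotypes(sc)$dosages,
                   simulate_genotypes(sc2)$dosages)
})
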