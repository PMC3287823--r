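test_that("the generator is deterministic given its seed", {
  c1 <- small_cohort(seed = 42)
  c2 <- small_cohort(seed = 42)
  expect_identical(unclass(c1$geno), unclass(c2$geno))
  expect_identical(c1$variants, c2$variants)
  expect_identical(unclass(c1$replicates), unclass(c2$replicates))
  expect_identical(c1$covariates, c2$covariates)
  c3 <- small_cohort(seed = 43)
  expect_false(identical(unclass(c1$geno), unclass(c3$geno)))
})

test_that("the default MAF spectrum reproduces the rare-skewed strata", {
  coh <- generate_cohort(cohort_config(n_variants = 5000L,
                                       n_replicates = 1L, seed = 2))
  frac_rare <- mean(coh$variants$maf < 0.05)
  expect_lt(abs(frac_rare - 0.872), 0.03)
  expect_gt(mean(coh$variants$maf < 0.01), 0.60)
})

test_that("null cohorts hit the baseline case rate from the logistic model", {
  beta0 <- -1
  cc <- cohort_config(n_subjects = 300L, n_variants = 50L, n_genes = 5L,
                      n_chromosomes = 1L, n_populations = 2L,
                      beta0 = beta0, beta_age = 0, beta_sex = 0,
                      beta_smoke = 0, n_replicates = 50L, seed = 8)
  coh <- generate_cohort(cc)
  expected <- 1 / (1 + exp(-beta0))
  observed <- mean(coh$replicates)
  n_draws <- length(coh$replicates)
  mc_err <- 3 * sqrt(expected * (1 - expected) / n_draws)
  expect_lt(abs(observed - expected), mc_err)
})

test_that("phenotype replicates are exchangeable on fixed genotypes", {
  coh <- small_cohort(seed = 31, n_subjects = 200, n_replicates = 40)
  case_rates <- colMeans(coh$replicates)
  p <- mean(case_rates)
  # each replicate's case count is an independent draw around the same mean
  expect_true(all(abs(case_rates - p) <
                    4 * sqrt(p * (1 - p) / nrow(coh$replicates))))
})

test_that("carrier prevalence tracks 1 - (1 - maf)^2", {
  cc <- cohort_config(n_subjects = 4000L, n_variants = 60L, n_genes = 5L,
                      n_chromosomes = 1L, n_populations = 1L,
                      maf_spectrum = c(0, 0, 1, 0), n_replicates = 1L,
                      seed = 12)
  coh <- generate_cohort(cc)
  carrier <- colMeans(make_dummies(coh$geno))
  expected <- 1 - (1 - coh$variants$maf)^2
  expect_lt(max(abs(carrier - expected)), 0.03)
})

test_that("causal genes shift case risk for carriers and fill the truth", {
  cc <- cohort_config(n_subjects = 800L, n_variants = 300L, n_genes = 20L,
                      n_chromosomes = 2L, n_populations = 2L,
                      causal_genes = list(list(gene = 2, beta = 2.0)),
                      causal_maf_range = c(0.01, 0.03),
                      n_replicates = 20L, seed = 6)
  coh <- generate_cohort(cc)
  expect_equal(nrow(coh$truth$causal_genes), 1L)
  expect_gt(length(coh$truth$causal_variants), 0L)
  carrier <- rowSums(make_dummies(
    coh$geno[, coh$truth$causal_variants, drop = FALSE])) > 0
  rate_carrier <- mean(coh$replicates[carrier, ])
  rate_other <- mean(coh$replicates[!carrier, ])
  expect_gt(rate_carrier, rate_other + 0.1)
})

test_that("infeasible causal gene indices are rejected", {
  expect_error(cohort_config(n_genes = 5L,
                             causal_genes = list(list(gene = 9, beta = 1))),
               "outside")
  expect_error(cohort_config(maf_spectrum = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
})
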