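null_usage <- function(counts, s, M = length(counts)) {
  structure(list(counts = setNames(as.integer(counts),
                                   sprintf("m%03d", seq_along(counts))),
                 split_counts = setNames(as.integer(counts),
                                         sprintf("m%03d",
                                                 seq_along(counts))),
                 s = s, S = sum(s), M = M, n_trees = length(s),
                 covariate_splits = 0L),
            class = "usage_counts")
}

test_that("binomial critical values match exhaustive CDF summation", {
  expect_equal(binomial_critical_value(0, 10), 0L)
  expect_equal(binomial_critical_value(10, 2, 0.1),
               binom_crit_oracle(10, 2, 0.1))
  for (M in c(2, 5, 10, 50)) {
    S_grid <- c(1:20, seq(25, 500, by = 12))
    ours <- vapply(S_grid, binomial_critical_value, integer(1), M = M,
                   alpha = 0.05)
    oracle <- vapply(S_grid, binom_crit_oracle, integer(1), M = M,
                     alpha = 0.05)
    expect_identical(ours, oracle)
  }
})

test_that("the critical value is monotone in S and in 1/alpha", {
  crit_S <- vapply(seq(0, 400, by = 7), binomial_critical_value, integer(1),
                   M = 25, alpha = 0.05)
  expect_true(all(diff(crit_S) >= 0))
  crit_a <- vapply(c(0.2, 0.1, 0.05, 0.01, 0.001), function(a)
    binomial_critical_value(300, 25, a), integer(1))
  expect_true(all(diff(crit_a) >= 0))
})

test_that("markers meeting or exceeding the critical value are flagged", {
  u <- null_usage(c(55, 14, 13, rep(2, 490)), s = rep(11, 199))
  u$S <- 2263L
  res <- call_significant(u, significance_config(alpha = 0.05))
  expect_equal(res$critical_value, 14L)
  tab <- res$table
  expect_true(tab$significant[tab$count == 55])
  expect_true(tab$significant[tab$count == 14])   # boundary equality
  expect_false(tab$significant[tab$count == 13])
})

test_that("an ensemble with no splits declares nothing significant", {
  u <- null_usage(rep(0, 20), s = rep(0, 10))
  res <- call_significant(u)
  expect_equal(res$critical_value, 0L)
  expect_false(any(res$table$significant))
})

test_that("permutations preserve case totals and are seed-reproducible", {
  withr::with_seed(61, {
    n <- 150
    vals <- matrix(rnorm(n * 5), n, 5,
                   dimnames = list(sprintf("s%d", 1:n),
                                   sprintf("m%03d", 1:5)))
    markers <- lapply(colnames(vals), function(id)
      list(marker_id = id, group_id = id, members = "v", weights = 1))
    ms <- marker_set(markers, vals)
    y <- rbinom(n, 1, 0.3)
    cfg <- significance_config(method = "permutation",
                               n_permutations = 30L, seed = 4L)
    p1 <- permutation_null(ms, NULL, y, config = cfg)
    p2 <- permutation_null(ms, NULL, y, config = cfg)
    expect_identical(p1$max_counts, p2$max_counts)
    expect_identical(p1$critical_value, p2$critical_value)
    expect_true(all(p1$p_values > 0 & p1$p_values <= 1))
    # a different seed gives a different permutation stream
    p3 <- permutation_null(ms, NULL, y,
                           config = significance_config(
                             method = "permutation",
                             n_permutations = 30L, seed = 5L))
    expect_false(identical(p1$max_counts, p3$max_counts))
  })
})

test_that("the permutation null controls family-wise error on null data", {
  n_seeds <- 40
  any_sig <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    coh <- generate_cohort(cohort_config(
      n_subjects = 200L, n_variants = 200L, n_genes = 20L,
      n_chromosomes = 2L, n_populations = 2L, beta_age = 0, beta_sex = 0,
      beta_smoke = 0, intergenic_rate = 0, n_replicates = 1L,
      seed = 700 + s))
    groups <- assign_groups(coh$variants, min_gene_size = 2)
    ms <- burden_marker_set(coh$geno, groups, prevalence_min = 0)
    pn <- permutation_null(ms, NULL, coh$replicates[, 1],
                           config = significance_config(
                             method = "permutation",
                             n_permutations = 60L, seed = s))
    any_sig[s] <- any(pn$observed >= pn$critical_value &
                        pn$critical_value > 0)
  }
  mc_err <- 2 * sqrt(0.05 * 0.95 / n_seeds)
  expect_lte(mean(any_sig), 0.05 + mc_err)
})
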