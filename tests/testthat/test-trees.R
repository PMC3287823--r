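# marker sets with hand-picked values for driving tree behaviour
feature_marker_set <- function(values) {
  markers <- lapply(colnames(values), function(id)
    list(marker_id = id, group_id = paste0("g_", id),
         members = paste0("v_", id), weights = 1))
  marker_set(markers, values)
}

test_that("a constant phenotype yields a stump with zero splits", {
  n <- 60
  vals <- matrix(rbinom(n, 1, 0.3), n, 1,
                 dimnames = list(sprintf("s%d", 1:n), "m001"))
  ms <- feature_marker_set(vals)
  tr <- fit_tree(ms, NULL, rep(0L, n))
  expect_equal(tr$n_splits, 0L)
})

test_that("the root split matches an exhaustive Gini-gain search", {
  withr::with_seed(23, {
    for (i in 1:5) {
      n <- 120
      vals <- cbind(matrix(rnorm(n * 7), n, 7),
                    rbinom(n, 1, 0.5), rbinom(n, 1, 0.2))
      colnames(vals) <- sprintf("m%03d", 1:9)
      rownames(vals) <- sprintf("s%d", 1:n)
      strength <- vals[, 3] + rnorm(n)
      y <- as.integer(strength > median(strength))
      ms <- feature_marker_set(vals)
      tr <- fit_tree(ms, NULL, y)
      oracle <- best_gini_split(as.data.frame(vals), y)
      expect_equal(tr$splits[1], oracle$feature)
    }
  })
})

test_that("a perfectly separating marker is the root split", {
  n <- 80
  sep <- rep(c(0, 1), each = n / 2)
  vals <- cbind(m001 = rnorm(n), m002 = sep, m003 = rnorm(n))
  rownames(vals) <- sprintf("s%d", 1:n)
  ms <- feature_marker_set(vals)
  tr <- fit_tree(ms, NULL, as.integer(sep))
  expect_equal(tr$splits, "m002")
  expect_equal(tr$n_splits, 1L)
})

test_that("nodes below the minimum size are not split", {
  n <- 19  # below the default min_node_to_split of 20
  vals <- matrix(rep(c(0, 1), length.out = n), n, 1,
                 dimnames = list(sprintf("s%d", 1:n), "m001"))
  ms <- feature_marker_set(vals)
  y <- as.integer(vals[, 1])
  tr <- fit_tree(ms, NULL, y)
  expect_equal(tr$n_splits, 0L)
})

test_that("tree fits are deterministic and sized by their internal nodes", {
  coh <- small_cohort(seed = 27, n_subjects = 250, n_variants = 200)
  groups <- assign_groups(filter_variants(coh$geno, coh$variants)$variants)
  ms <- burden_marker_set(filter_variants(coh$geno, coh$variants)$geno,
                          groups, prevalence_min = 0)
  t1 <- fit_tree(ms, coh$covariates, coh$replicates[, 2])
  t2 <- fit_tree(ms, coh$covariates, coh$replicates[, 2])
  expect_identical(t1$splits, t2$splits)
  expect_equal(t1$n_splits,
               sum(as.character(t1$rpart$frame$var) != "<leaf>"))
})

test_that("usage counting distinguishes markers from covariates", {
  withr::with_seed(33, {
    n <- 240
    A <- as.numeric(seq_len(n) <= 80)
    B <- as.numeric(seq_len(n) %in% 81:120)
    C <- as.numeric(seq_len(n) %in% c(1:30, 121:150))  # useless for A | B
    vals <- cbind(m_A = A, m_B = B, m_C = C)
    rownames(vals) <- sprintf("s%d", 1:n)
    ms <- feature_marker_set(vals)
    # replicate 1 needs A and B, replicate 2 only A, replicate 3 only C
    reps <- phenotype_replicates(
      cbind(as.integer(A | B), as.integer(A), as.integer(C), as.integer(A)),
      subject_ids = rownames(vals))
    usage <- run_ensemble(ms, NULL, reps, construction_replicate = 4L)
    expect_equal(unname(usage$counts[c("m_A", "m_B", "m_C")]),
                 c(2L, 1L, 1L))
    expect_equal(usage$S, sum(usage$s))
    expect_equal(usage$n_trees, 3L)
    expect_equal(usage$covariate_splits, 0L)
  })
})

test_that("covariate splits count toward S but never toward markers", {
  withr::with_seed(35, {
    n <- 200
    covs <- random_covariates(n, seed = 9)
    vals <- matrix(rnorm(n), n, 1,
                   dimnames = list(covs$subject_id, "m001"))
    ms <- feature_marker_set(vals)
    y <- covs$sex  # phenotype driven purely by a covariate
    reps <- phenotype_replicates(cbind(y, y),
                                 subject_ids = covs$subject_id)
    usage <- run_ensemble(ms, covs, reps, construction_replicate = 1L)
    expect_equal(unname(usage$counts["m001"]), 0L)
    expect_gte(usage$covariate_splits, 1L)
    expect_equal(usage$S, usage$covariate_splits)
  })
})

test_that("null per-split usage is consistent with the Bin(S, 1/M) model", {
  # exchangeable null markers: goodness-of-fit should hold in most seeds
  n_seeds <- 12
  ok <- logical(n_seeds)
  withr::local_seed(55)
  for (s in seq_len(n_seeds)) {
    cc <- cohort_config(n_subjects = 300L, n_variants = 600L, n_genes = 40L,
                        n_chromosomes = 2L, n_populations = 2L,
                        maf_spectrum = c(0, 0.5, 0.5, 0), beta_age = 0,
                        beta_sex = 0, beta_smoke = 0,
                        intergenic_rate = 0, n_replicates = 60L,
                        seed = 100 + s)
    coh <- generate_cohort(cc)
    groups <- assign_groups(coh$variants, min_gene_size = 2)
    ms <- burden_marker_set(coh$geno, groups, prevalence_min = 0)
    usage <- run_ensemble(ms, NULL, coh$replicates)
    counts <- usage$split_counts
    # conditional on S, the null split counts are Multinomial(S, 1/M);
    # Monte-Carlo goodness-of-fit copes with small expected counts
    gof <- suppressWarnings(
      stats::chisq.test(counts, p = rep(1 / usage$M, usage$M),
                        simulate.p.value = TRUE, B = 999))
    ok[s] <- gof$p.value > 0.01
  }
  expect_gte(mean(ok), 0.9)
})
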