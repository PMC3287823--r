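lasso_toy <- function(seed = 1, n = 200, k = 10, p_case = 0.3) {
  withr::with_seed(seed, list(
    D = matrix(rbinom(n * k, 1, 0.08), n, k,
               dimnames = list(NULL, sprintf("d%02d", 1:k))),
    Z = build_covariate_design(random_covariates(n, seed = seed + 100)),
    y = rbinom(n, 1, p_case)))
}

test_that("carrier dummies code presence of the minor allele", {
  calls <- matrix(c(0L, 1L, 2L, NA, 0L, 2L), 3, 2,
                  dimnames = list(c("a", "b", "c"), c("v1", "v2")))
  d <- make_dummies(genotype_matrix(calls))
  expect_equal(unname(d[, "v1"]), c(0L, 1L, 1L))
  expect_equal(unname(d[, "v2"]), c(0L, 0L, 1L))  # missing -> non-carrier
  expect_true(all(d %in% 0:1))
})

test_that("the top of the path is the covariates-only model", {
  toy <- lasso_toy(2)
  fit <- fit_lasso_logistic(toy$D, toy$Z, toy$y)
  expect_true(all(fit$beta[fit$penalized, 1] == 0))
  ref <- glm.fit(toy$Z, toy$y, family = binomial())$coefficients
  expect_equal(unname(fit$beta[!fit$penalized, 1]), unname(ref),
               tolerance = 1e-6)
})

test_that("lambda_max matches a finite-difference gradient oracle", {
  toy <- lasso_toy(3)
  fit0 <- glm(toy$y ~ toy$Z - 1, family = binomial())
  beta0 <- unname(coef(fit0))
  eps <- 1e-5
  loglik_at <- function(bd, j) {
    eta <- toy$Z %*% beta0 + toy$D[, j] * bd
    p <- 1 / (1 + exp(-eta))
    sum(toy$y * log(p) + (1 - toy$y) * log(1 - p))
  }
  grad <- vapply(seq_len(ncol(toy$D)), function(j)
    (loglik_at(eps, j) - loglik_at(-eps, j)) / (2 * eps), numeric(1))
  fit <- fit_lasso_logistic(toy$D, toy$Z, toy$y)
  expect_equal(fit$lambda_max, max(abs(grad)), tolerance = 1e-5)
})

test_that("the strongest dummy enters the path first", {
  withr::with_seed(4, {
    n <- 300
    D <- matrix(rbinom(n * 10, 1, 0.1), n, 10)
    y <- D[, 7]  # perfectly correlated with dummy 7
    Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    # perfect separation at small lambda is expected here
    fit <- suppressWarnings(fit_lasso_logistic(D, Z, y))
    first_nonzero <- apply(fit$beta[fit$penalized, ], 1,
                           function(b) {
                             nz <- which(b != 0)
                             if (length(nz)) min(nz) else Inf
                           })
    expect_equal(unname(which.min(first_nonzero)), 7L)
  })
})

test_that("every path point satisfies the KKT conditions to 1e-6", {
  for (s in 1:5) {
    toy <- lasso_toy(s + 10, n = 150, k = 8)
    fit <- fit_lasso_logistic(toy$D, toy$Z, toy$y)
    expect_lt(max(fit$kkt), 1e-6)
  }
})

test_that("path solutions agree with an independent penalized solver", {
  skip_if_not_installed("glmnet")
  toy <- lasso_toy(6, n = 250, k = 12)
  fit <- fit_lasso_logistic(toy$D, toy$Z, toy$y)
  Xg <- cbind(toy$Z[, -1], toy$D)
  pf <- c(rep(0, ncol(toy$Z) - 1), rep(1, ncol(toy$D)))
  scale_pf <- length(pf) / sum(pf)
  for (i in c(15, 50, 90)) {
    g <- glmnet::glmnet(Xg, toy$y, family = "binomial", penalty.factor = pf,
                        standardize = FALSE, thresh = 1e-14, maxit = 1e6,
                        lambda = fit$lambda[i] / (nrow(Xg) * scale_pf))
    ours <- unname(c(fit$beta[1, i], fit$beta[-1, i]))
    expect_equal(ours, as.numeric(stats::coef(g)), tolerance = 1e-5)
  }
})

test_that("AIC selection follows 2k - 2loglik with ties to larger lambda", {
  mk_fit <- function(loglik, df, lambda = rev(seq_along(loglik))) {
    structure(list(lambda = lambda, loglik = loglik, df = df,
                   beta = matrix(seq_along(loglik), 1),
                   aic = 2 * df - 2 * loglik,
                   selected = which.min(2 * df - 2 * loglik),
                   penalized = FALSE),
              class = "lasso_path")
  }
  fit <- mk_fit(loglik = c(-100, -95, -94.9), df = c(5, 6, 7))
  expect_equal(fit$aic, c(210, 202, 203.8))
  expect_equal(attr(select_by_aic(fit), "index"), 2L)
  single <- mk_fit(loglik = -50, df = 3)
  expect_equal(attr(select_by_aic(single), "index"), 1L)
  tied <- mk_fit(loglik = c(-100, -101), df = c(5, 4))
  expect_equal(fit$aic[1], 210)
  expect_equal(attr(select_by_aic(tied), "index"), 1L)  # sparsest on tie
})

test_that("markers below the prevalence floor are rejected", {
  withr::with_seed(8, {
    n <- 200
    # one strong dummy carried by only 4% of subjects
    d <- integer(n); d[1:8] <- 1L
    calls <- cbind(v1 = d, v2 = integer(n))
    rownames(calls) <- sprintf("s%d", 1:n)
    geno <- genotype_matrix(calls)
    vt <- variant_table(c("v1", "v2"), "chr1", c(1L, 2L), c("A", "A"), 0.02)
    groups <- assign_groups(vt, min_gene_size = 2, bin_size = 5)
    y <- integer(n); y[1:8] <- 1L; y[9:60] <- rep(c(0L, 1L), 26)
    ms5 <- build_composite_markers(geno, groups, NULL, y,
                                   prevalence_min = 0.05)
    expect_length(ms5, 0L)
    ms3 <- build_composite_markers(geno, groups, NULL, y,
                                   prevalence_min = 0.03)
    expect_length(ms3, 1L)
    expect_gte(min(marker_prevalence(ms3)), 0.03)
  })
})

test_that("marker values are the weighted carrier combinations", {
  ms <- marker_set(list(list(marker_id = "m001", group_id = "g",
                             members = c("v1", "v2"),
                             weights = c(0.5, -0.2))),
                   matrix(c(0.5, 0, -0.2, 0.3), 4, 1,
                          dimnames = list(sprintf("s%d", 1:4), NULL)))
  d <- c(v1 = 1, v2 = 0)
  expect_equal(sum(ms$markers[[1]]$weights * d), 0.5)
})

test_that("built markers always satisfy the prevalence invariant", {
  coh <- small_cohort(seed = 19, n_subjects = 200, n_variants = 250,
                      causal = list(list(gene = 1, beta = 1.5)))
  qc <- filter_variants(coh$geno, coh$variants)
  groups <- assign_groups(qc$variants)
  ms <- build_composite_markers(qc$geno, groups, coh$covariates,
                                coh$replicates[, 1])
  if (length(ms) > 0) {
    expect_gte(min(marker_prevalence(ms)), 0.05)
    diag <- attr(ms, "diagnostics")
    expect_true(all(diag$n_selected[diag$kept] >= 1))
  }
  # groups with no selected dummies emit no marker
  expect_lte(length(ms), length(unique(groups$group_id)))
})
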