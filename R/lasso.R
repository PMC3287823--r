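#' Carrier (dominant) coding of a genotype group
#'
#' One 0/1 dummy per variant: 1 iff the subject carries at least one copy of
#' the minor allele (call 1 or 2). Missing calls code as 0 (non-carrier).
#'
#' @param geno A [genotype_matrix()] restricted to one group's variants.
#' @return Integer 0/1 matrix, same dimnames as `geno`.
#' @export
make_dummies <- function(geno) {
  d <- (unclass(geno) >= 1L)
  d[is.na(d)] <- FALSE
  storage.mode(d) <- "integer"
  d
}

#' Unpenalized covariate design matrix
#'
#' Intercept, one-hot population indicators (largest population as the
#' reference level), age, sex and smoking. These columns enter every
#' penalized fit unpenalized.
#'
#' @param covariates A [covariate_table()], or `NULL` for an intercept-only
#'   design.
#' @param n_subjects Number of subjects, required when `covariates` is `NULL`.
#' @return Numeric design matrix with an `(Intercept)` column.
#' @export
build_covariate_design <- function(covariates, n_subjects = NULL) {
  if (is.null(covariates)) {
    stopifnot(!is.null(n_subjects))
    return(matrix(1, n_subjects, 1, dimnames = list(NULL, "(Intercept)")))
  }
  pop <- covariates$population
  ref <- names(which.max(table(pop)))
  pop <- stats::relevel(factor(pop), ref = ref)
  stats::model.matrix(~ pop + age + sex + smoking,
                      data = data.frame(pop = pop, age = covariates$age,
                                        sex = covariates$sex,
                                        smoking = covariates$smoking))
}

#' L1-penalized logistic regression path with unpenalized covariates
#'
#' Maximizes `loglik(beta) - lambda * sum(|beta_dummy|)` by iteratively
#' reweighted least squares with cyclic coordinate descent, over a decreasing
#' path of 100 log-spaced penalties from `lambda_max` (the smallest penalty
#' at which every penalized coefficient is zero) down to
#' `lambda_min_ratio * lambda_max`, warm-starting each fit from the previous
#' one. The intercept and covariate columns are never penalized. Dummies are
#' not standardized: they are comparable 0/1 variables and unstandardized
#' weights stay interpretable as per-carrier contributions.
#'
#' Each path solution is certified against the Karush-Kuhn-Tucker conditions:
#' for zero penalized coefficients `|score_j| <= lambda + tol`, for nonzero
#' ones `score_j = lambda * sign(beta_j)` within `tol`, and zero score for
#' unpenalized columns.
#'
#' @param dummies 0/1 carrier matrix from [make_dummies()] (penalized).
#' @param covariate_design Matrix from [build_covariate_design()]
#'   (unpenalized, includes the intercept).
#' @param phenotype 0/1 vector with at least one case and one control.
#' @param nlambda Number of path points (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of `lambda_max`
#'   (default 0.001).
#' @param tol Coordinate-descent convergence tolerance (default 1e-10).
#' @param beta_cap Absolute coefficient bound; hitting it signals separation
#'   and triggers a warning (default 100).
#' @return An object of class `lasso_path`: `lambda` (decreasing), `beta`
#'   (coefficients x path points; covariates first, then dummies), `loglik`,
#'   `df` (nonzero coefficients including the unpenalized ones), `aic`
#'   (`2 df - 2 loglik`), `selected` (AIC-minimizing index, ties to the
#'   largest penalty), `kkt` (max KKT violation per path point), `penalized`
#'   (logical per coefficient).
#' @export
fit_lasso_logistic <- function(dummies, covariate_design, phenotype,
                               nlambda = 100L, lambda_min_ratio = 0.001,
                               tol = 1e-10, beta_cap = 100) {
  y <- as.numeric(phenotype)
  stopifnot(all(y %in% 0:1))
  if (sum(y) == 0 || sum(y) == length(y))
    stop("phenotype needs at least one case and one control")
  Z <- as.matrix(covariate_design)
  D <- as.matrix(dummies)
  storage.mode(D) <- "double"
  if (qr(Z)$rank < ncol(Z)) stop("covariate design is rank deficient")
  X <- cbind(Z, D)
  penalized <- c(rep(FALSE, ncol(Z)), rep(TRUE, ncol(D)))
  n <- nrow(X)

  # covariates-only fit anchors the top of the path
  fit0 <- glm.fit(Z, y, family = binomial())
  beta <- c(fit0$coefficients, rep(0, ncol(D)))
  p0 <- fit0$fitted.values
  score0 <- as.numeric(crossprod(D, y - p0))
  lambda_max <- max(abs(score0))
  if (lambda_max <= 0) lambda_max <- 1e-8  # no dummy carries signal at all
  lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = nlambda))

  # at lambda_max the covariates-only fit IS the solution (all penalized
  # coefficients exactly 0); solve the rest of the path from that warm start
  if (nlambda > 1L) {
    cd <- .cd_logistic_path(X, y, penalized, lambda[-1], beta, tol, beta_cap)
    betas <- cbind(beta, cd$beta)
  } else {
    cd <- list(capped = FALSE)
    betas <- matrix(beta, ncol = 1L)
  }
  dimnames(betas) <- list(colnames(X), NULL)
  if (any(cd$capped))
    warning("coefficients capped at ", beta_cap,
            " (possible separation at small lambda)")
  eta <- pmin(pmax(X %*% betas, -30), 30)
  prob <- 1 / (1 + exp(-eta))
  loglik <- colSums(y * log(prob) + (1 - y) * log(1 - prob))
  df <- colSums(betas != 0)
  scores <- crossprod(X, y - prob)  # coefficients x path points
  viol <- matrix(0, nrow(scores), ncol(scores))
  lam_mat <- matrix(lambda, nrow(scores), ncol(scores), byrow = TRUE)
  zero <- betas == 0
  viol[!penalized, ] <- abs(scores[!penalized, , drop = FALSE])
  pz <- penalized & zero
  viol[pz] <- pmax(abs(scores[pz]) - lam_mat[pz], 0)
  pnz <- penalized & !zero
  viol[pnz] <- abs(scores[pnz] - lam_mat[pnz] * sign(betas[pnz]))
  kkt <- apply(viol, 2, max)
  aic <- 2 * df - 2 * loglik
  selected <- which.min(aic)  # first minimum = largest lambda on ties
  structure(list(lambda = lambda, beta = betas, loglik = loglik, df = df,
                 aic = aic, selected = selected, kkt = kkt,
                 penalized = penalized, lambda_max = lambda_max),
            class = "lasso_path")
}

#' Maximum Karush-Kuhn-Tucker violation of a penalized logistic solution
#'
#' @param X Full design matrix (covariates then dummies).
#' @param y 0/1 response.
#' @param beta Coefficient vector.
#' @param lambda Penalty.
#' @param penalized Logical per coefficient.
#' @return Largest absolute violation of the stationarity conditions.
#' @export
kkt_violation <- function(X, y, beta, lambda, penalized) {
  eta <- pmin(pmax(as.numeric(X %*% beta), -30), 30)
  p <- 1 / (1 + exp(-eta))
  score <- as.numeric(crossprod(X, y - p))
  v_unpen <- abs(score[!penalized])
  sp <- score[penalized]
  bp <- beta[penalized]
  v_zero <- pmax(abs(sp[bp == 0]) - lambda, 0)
  v_nz <- abs(sp[bp != 0] - lambda * sign(bp[bp != 0]))
  max(c(0, v_unpen, v_zero, v_nz))
}

#' Coefficients at the AIC-optimal point of a penalty path
#'
#' Picks the path point minimizing `AIC = 2k - 2 loglik`, with `k` counting
#' every nonzero coefficient including the intercept and the unpenalized
#' covariates (a constant offset that cannot change the argmin, but keeps the
#' reported AIC reproducible). Ties go to the largest penalty, i.e. the
#' sparsest model.
#'
#' @param fit A `lasso_path` from [fit_lasso_logistic()].
#' @return Named numeric vector of coefficients at the selected penalty, with
#'   attributes `lambda`, `aic`, `index`.
#' @export
select_by_aic <- function(fit) {
  stopifnot(inherits(fit, "lasso_path"))
  i <- fit$selected
  structure(fit$beta[, i],
            lambda = fit$lambda[i], aic = fit$aic[i], index = i)
}

#' Build composite markers from grouped rare variants
#'
#' The core collapsing step. For each group: code carrier dummies, fit the
#' penalized logistic path with unpenalized covariates on the designated
#' construction phenotype, pick the AIC-best penalty, and — if at least one
#' dummy was selected — emit the fitted linear combination
#' `v_j = sum_k beta_k d_jk` as a composite marker. Only markers that are
#' nonzero in at least `prevalence_min` of the subjects are kept, ensuring
#' the new markers are not themselves rare.
#'
#' @param geno QC-filtered [genotype_matrix()].
#' @param groups `group_assignment` from [assign_groups()].
#' @param covariates A [covariate_table()] or `NULL`.
#' @param phenotype 0/1 construction-replicate phenotype vector.
#' @param prevalence_min Minimum fraction of subjects with a nonzero marker
#'   value (default 0.05).
#' @param weighting `"lasso"` (default) uses the fitted coefficients as
#'   weights; `"union"` re-thresholds to a 0/1 carrier-union marker over the
#'   selected variants.
#' @param nlambda,lambda_min_ratio Path specification, see
#'   [fit_lasso_logistic()].
#' @param verbose Emit per-stage messages.
#' @return A [marker_set()]; its `diagnostics` attribute is a per-group
#'   data.frame (group_id, n_variants, lambda, df, loglik, aic, n_selected,
#'   prevalence, kept).
#' @export
build_composite_markers <- function(geno, groups, covariates, phenotype,
                                    prevalence_min = 0.05,
                                    weighting = c("lasso", "union"),
                                    nlambda = 100L, lambda_min_ratio = 0.001,
                                    verbose = FALSE) {
  weighting <- match.arg(weighting)
  members <- group_members(groups)
  Z <- build_covariate_design(covariates, n_subjects = nrow(geno))
  markers <- list()
  values <- matrix(numeric(0), nrow = nrow(geno), ncol = 0,
                   dimnames = list(rownames(geno), NULL))
  diag_rows <- list()
  for (gid in names(members)) {
    vars <- members[[gid]]
    D <- make_dummies(geno[, vars, drop = FALSE])
    rec <- list(group_id = gid, n_variants = length(vars), lambda = NA_real_,
                df = NA_real_, loglik = NA_real_, aic = NA_real_,
                n_selected = 0L, prevalence = NA_real_, kept = FALSE)
    if (all(colSums(D) == 0L)) {
      rl_log("group %s: no carriers at all, skipped", gid, verbose = verbose)
      diag_rows[[gid]] <- rec
      next
    }
    fit <- fit_lasso_logistic(D, Z, phenotype, nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio)
    coefs <- select_by_aic(fit)
    rec$lambda <- attr(coefs, "lambda")
    rec$aic <- attr(coefs, "aic")
    rec$df <- fit$df[fit$selected]
    rec$loglik <- fit$loglik[fit$selected]
    w <- coefs[fit$penalized]
    nz <- which(w != 0)
    rec$n_selected <- length(nz)
    if (length(nz)) {
      weights <- if (weighting == "lasso") unname(w[nz])
                 else rep(1, length(nz))
      v <- as.numeric(D[, nz, drop = FALSE] %*% weights)
      if (weighting == "union") v <- as.numeric(v > 0)
      rec$prevalence <- mean(v != 0)
      if (rec$prevalence >= prevalence_min) {
        rec$kept <- TRUE
        markers[[length(markers) + 1L]] <-
          list(marker_id = sprintf("m%03d", length(markers) + 1L),
               group_id = gid, members = vars[nz], weights = weights)
        values <- cbind(values, v)
      }
    }
    diag_rows[[gid]] <- rec
  }
  ms <- marker_set(markers, values)
  attr(ms, "diagnostics") <- do.call(rbind, lapply(diag_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rl_log("built %d composite markers from %d groups", length(markers),
         length(members), verbose = verbose)
  ms
}

#' Unit-weight burden markers
#'
#' The classical collapsing baseline: one marker per group whose value is the
#' subject's count of carried group variants (all weights 1, no selection).
#' Useful as a comparison and for constructing exchangeable null markers.
#'
#' @inheritParams build_composite_markers
#' @return A [marker_set()]; groups below `prevalence_min` are dropped.
#' @export
burden_marker_set <- function(geno, groups, prevalence_min = 0.05) {
  members <- group_members(groups)
  markers <- list()
  values <- matrix(numeric(0), nrow = nrow(geno), ncol = 0,
                   dimnames = list(rownames(geno), NULL))
  for (gid in names(members)) {
    vars <- members[[gid]]
    D <- make_dummies(geno[, vars, drop = FALSE])
    v <- as.numeric(rowSums(D))
    if (mean(v != 0) < prevalence_min) next
    markers[[length(markers) + 1L]] <-
      list(marker_id = sprintf("m%03d", length(markers) + 1L),
           group_id = gid, members = vars, weights = rep(1, length(vars)))
    values <- cbind(values, v)
  }
  marker_set(markers, values)
}
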