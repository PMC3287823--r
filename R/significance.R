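#' Significance-testing settings
#'
#' @param alpha Family-wise significance level (default 0.05), Bonferroni
#'   corrected across the M markers.
#' @param method `"binomial"` (split-frequency null) or `"permutation"`.
#' @param n_permutations Number of phenotype permutations for the
#'   permutation null (default 500).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `significance_config`.
#' @export
significance_config <- function(alpha = 0.05,
                                method = c("binomial", "permutation"),
                                n_permutations = 500L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 1L)
  structure(list(alpha = alpha, method = match.arg(method),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "significance_config")
}

#' Critical usage count under the binomial split-frequency null
#'
#' Under the null of no marker-phenotype association, each of the `S` splits
#' in the ensemble picks any given marker with probability `1/M`, so a
#' marker's total count is Binomial(S, 1/M). The Bonferroni-corrected
#' critical value is the `1 - alpha/M` quantile of that distribution: the
#' smallest integer `q` whose CDF is at least `1 - alpha/M`. A marker whose
#' count meets or exceeds `q` is genome-wide significant.
#'
#' @param S Total number of splits across the ensemble (`sum(s_i)`).
#' @param M Number of candidate markers.
#' @param alpha Family-wise level before the Bonferroni division by `M`.
#' @return Integer critical count; 0 when `S = 0`.
#' @export
binomial_critical_value <- function(S, M, alpha = 0.05) {
  stopifnot(S >= 0, M >= 1, alpha > 0, alpha < 1)
  if (S == 0) return(0L)
  as.integer(qbinom(1 - alpha / M, size = S, prob = 1 / M))
}

#' Flag significant markers from ensemble usage counts
#'
#' Applies the binomial split-frequency null: a marker is significant when
#' its usage count meets or exceeds [binomial_critical_value()] (boundary
#' equality is significant). An ensemble with no splits at all declares
#' nothing significant.
#'
#' @param usage A `usage_counts` object from [run_ensemble()].
#' @param config A [significance_config()].
#' @param convention Which counting convention to test: `"distinct"`
#'   (default, once per tree) or `"splits"` (every split).
#' @return An object of class `significance_result`: `table` (marker_id,
#'   count, significant), `critical_value`, `S`, `M`, `alpha`,
#'   `per_marker_alpha`, `method`.
#' @export
call_significant <- function(usage, config = significance_config(),
                             convention = c("distinct", "splits")) {
  stopifnot(inherits(usage, "usage_counts"))
  convention <- match.arg(convention)
  counts <- if (convention == "distinct") usage$counts else usage$split_counts
  q <- binomial_critical_value(usage$S, usage$M, config$alpha)
  # degenerate ensembles (q = 0) must not promote zero counts to significance
  sig <- if (usage$S == 0) rep(FALSE, length(counts))
         else counts >= max(q, 1L)
  tab <- data.frame(marker_id = names(counts), count = as.integer(counts),
                    critical_value = q, significant = sig,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$count, tab$marker_id), ]
  rownames(tab) <- NULL
  structure(list(table = tab, critical_value = q, S = usage$S, M = usage$M,
                 alpha = config$alpha,
                 per_marker_alpha = config$alpha / usage$M,
                 method = "binomial", convention = convention),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf(
    "significance_result (%s): S = %d, M = %d, alpha = %g (%g per marker)\n",
    x$method, x$S, x$M, x$alpha, x$per_marker_alpha))
  cat(sprintf("critical value: %d; %d marker(s) significant\n",
              x$critical_value, sum(x$table$significant)))
  print(head(x$table, 10))
  invisible(x)
}

#' Permutation null for single-replicate analyses
#'
#' When no phenotype replicates exist, significance can be assessed by
#' permuting affection status: each permutation shuffles the case/control
#' labels (preserving their totals), refits a classification tree on the
#' same markers and covariates, and records the maximum per-marker usage
#' count. The empirical family-wise critical value is the smallest count
#' whose tail probability under the max-count null does not exceed `alpha`
#' (the discrete-safe form of the `1 - alpha` null quantile), and per-marker
#' p-values are upper-tail probabilities of each observed count under the
#' max-count null.
#'
#' @param ms A [marker_set()].
#' @param covariates A [covariate_table()] or `NULL`.
#' @param phenotype 0/1 vector: the single analysis replicate.
#' @param spec A [tree_spec()].
#' @param config A [significance_config()]; uses `n_permutations`, `seed`,
#'   `alpha`.
#' @param convention Counting convention, as in [call_significant()].
#' @return An object of class `permutation_null`: `critical_value`,
#'   `max_counts` (one per permutation), `observed` (per-marker counts on
#'   the unpermuted phenotype), `p_values`, `alpha`, `n_permutations`.
#' @export
permutation_null <- function(ms, covariates, phenotype, spec = tree_spec(),
                             config = significance_config(),
                             convention = c("distinct", "splits")) {
  convention <- match.arg(convention)
  count_tree <- function(y) {
    tr <- fit_tree(ms, covariates, y, spec)
    ids <- vapply(ms$markers, function(m) m$marker_id, character(1))
    used <- tr$splits[tr$splits %in% ids]
    if (convention == "distinct") used <- unique(used)
    out <- setNames(integer(length(ids)), ids)
    tab <- table(used)
    out[names(tab)] <- as.integer(tab)
    out
  }
  observed <- count_tree(phenotype)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  max_counts <- vapply(seq_len(config$n_permutations), function(i) {
    perm <- sample(phenotype)
    max(c(0L, count_tree(perm)))
  }, integer(1))
  # smallest c with P_hat(max >= c) <= alpha; counts are integers, so the
  # continuous quantile rule would over-reject at ties
  crit <- 0L
  while (mean(max_counts >= crit) > config$alpha) crit <- crit + 1L
  pvals <- vapply(observed, function(o)
    (1 + sum(max_counts >= o)) / (1 + length(max_counts)), numeric(1))
  structure(list(critical_value = crit, max_counts = max_counts,
                 observed = observed, p_values = pvals,
                 alpha = config$alpha,
                 n_permutations = config$n_permutations,
                 method = "permutation"),
            class = "permutation_null")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
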