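#' Classification-tree settings
#'
#' Mirrors the stock CART defaults used for the association trees: Gini
#' impurity, a node must hold `min_node_to_split` subjects to be considered
#' for splitting, leaves keep at least `min_leaf` subjects, a split must
#' improve the fit by `complexity_penalty` of the root's, and depth is
#' capped at `max_depth`.
#'
#' @param min_node_to_split Minimum node size eligible for splitting
#'   (default 20).
#' @param min_leaf Minimum leaf size (default 7).
#' @param complexity_penalty Complexity parameter gating each split
#'   (default 0.01).
#' @param max_depth Maximum tree depth (default 30).
#' @return A list of class `tree_spec`.
#' @export
tree_spec <- function(min_node_to_split = 20L, min_leaf = 7L,
                      complexity_penalty = 0.01, max_depth = 30L) {
  stopifnot(complexity_penalty >= 0, min_leaf >= 1L,
            min_node_to_split >= 2L, max_depth >= 1L)
  structure(list(min_node_to_split = as.integer(min_node_to_split),
                 min_leaf = as.integer(min_leaf),
                 complexity_penalty = complexity_penalty,
                 max_depth = as.integer(max_depth)),
            class = "tree_spec")
}

tree_feature_frame <- function(ms, covariates) {
  df <- as.data.frame(ms$values, check.names = FALSE)
  if (!is.null(covariates)) {
    stopifnot(identical(as.character(covariates$subject_id),
                        rownames(ms$values)))
    df$population <- factor(covariates$population)
    df$age <- covariates$age
    df$sex <- covariates$sex
    df$smoking <- covariates$smoking
  }
  df
}

#' Fit one classification tree on markers plus covariates
#'
#' Greedy binary CART on Gini impurity via [rpart::rpart()] with the settings
#' in [tree_spec()] (and no internal cross-validation, so the fit is
#' deterministic given its inputs).
#'
#' @param ms A [marker_set()] providing the marker feature columns.
#' @param covariates A [covariate_table()] or `NULL`; covariates enter as
#'   candidate split variables but never count toward marker usage.
#' @param phenotype 0/1 vector aligned to the marker subjects.
#' @param spec A [tree_spec()].
#' @return An object of class `fitted_tree` with `splits` (split-variable
#'   names, one per internal node), `n_splits` (`s_i`), and `rpart` (the
#'   underlying fit).
#' @export
fit_tree <- function(ms, covariates, phenotype, spec = tree_spec()) {
  df <- tree_feature_frame(ms, covariates)
  if (ncol(df) == 0L || length(unique(phenotype)) < 2L) {
    return(structure(list(splits = character(0), n_splits = 0L, rpart = NULL),
                     class = "fitted_tree"))
  }
  df$.affected <- factor(phenotype, levels = c(0, 1))
  ctrl <- rpart::rpart.control(minsplit = spec$min_node_to_split,
                               minbucket = spec$min_leaf,
                               cp = spec$complexity_penalty,
                               maxdepth = spec$max_depth,
                               xval = 0, maxsurrogate = 0,
                               maxcompete = 0)
  fit <- rpart::rpart(.affected ~ ., data = df, method = "class",
                      parms = list(split = "gini"), control = ctrl)
  vars <- as.character(fit$frame$var)
  splits <- vars[vars != "<leaf>"]
  structure(list(splits = splits, n_splits = length(splits), rpart = fit),
            class = "fitted_tree")
}

#' @export
print.fitted_tree <- function(x, ...) {
  cat(sprintf("fitted_tree: %d splits on {%s}\n", x$n_splits,
              paste(unique(x$splits), collapse = ", ")))
  invisible(x)
}

#' Fit the per-replicate tree ensemble and count marker usage
#'
#' Fits one classification tree per phenotype replicate, excluding the
#' replicate the markers were constructed on, and tallies how often each
#' marker is used as a splitting variable across the ensemble. Two counting
#' conventions are recorded: `distinct` counts a marker once per tree in
#' which it appears (the default downstream), `splits` counts every split
#' on it. Covariate splits contribute to the tree sizes `s_i` and to the
#' split total `S`, but never to marker usage.
#'
#' @param ms A [marker_set()].
#' @param covariates A [covariate_table()] or `NULL`.
#' @param replicates A [phenotype_replicates()] matrix with `R >= 2` columns.
#' @param construction_replicate Column index of the replicate used for
#'   marker construction; it is excluded from evaluation (default 1).
#' @param spec A [tree_spec()].
#' @return An object of class `usage_counts`: `counts` (distinct-per-tree,
#'   named per marker), `split_counts`, `s` (per-tree sizes `s_i`),
#'   `m_per_tree` (distinct markers used per tree), `S` (`sum(s)`), `M`,
#'   `n_trees`, `covariate_splits`.
#' @export
run_ensemble <- function(ms, covariates, replicates,
                         construction_replicate = 1L, spec = tree_spec()) {
  stopifnot(inherits(replicates, "phenotype_replicates"))
  R <- ncol(replicates)
  if (R < 2L)
    stop("need at least one evaluation replicate beyond the construction one")
  eval_idx <- setdiff(seq_len(R), construction_replicate)
  marker_ids <- vapply(ms$markers, function(m) m$marker_id, character(1))
  counts <- split_counts <- setNames(integer(length(marker_ids)), marker_ids)
  s <- m_per_tree <- integer(length(eval_idx))
  cov_splits <- 0L
  for (k in seq_along(eval_idx)) {
    tr <- fit_tree(ms, covariates, replicates[, eval_idx[k]], spec)
    s[k] <- tr$n_splits
    used <- tr$splits[tr$splits %in% marker_ids]
    cov_splits <- cov_splits + sum(!tr$splits %in% marker_ids)
    tab <- table(used)
    split_counts[names(tab)] <- split_counts[names(tab)] + as.integer(tab)
    u <- unique(used)
    m_per_tree[k] <- length(u)
    counts[u] <- counts[u] + 1L
  }
  structure(list(counts = counts, split_counts = split_counts, s = s,
                 m_per_tree = m_per_tree, S = sum(s),
                 M = length(marker_ids),
                 n_trees = length(eval_idx), covariate_splits = cov_splits),
            class = "usage_counts")
}

#' @export
print.usage_counts <- function(x, ...) {
  cat(sprintf(
    "usage_counts: %d trees, S = %d total splits over M = %d markers\n",
    x$n_trees, x$S, x$M))
  cat(sprintf("markers used per tree: mean %.2f (sd %.2f)\n",
              mean_markers_per_tree(x), stats::sd(x$m_per_tree)))
  invisible(x)
}

#' Mean number of markers used per tree
#' @param usage A `usage_counts` object.
#' @return `sum(distinct counts) / n_trees`.
#' @export
mean_markers_per_tree <- function(usage) {
  if (usage$n_trees == 0L) return(0)
  sum(usage$counts) / usage$n_trees
}
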