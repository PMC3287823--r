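#' Full-run configuration
#'
#' Bundles every stage's parameters plus input/output paths. All parameters
#' round-trip through [write_run_config()] / [read_run_config()] so an
#' emitted effective-config reproduces the run. A single global seed fans
#' out to per-stage seeds (`seed + fixed offsets`), keeping stages
#' independently reproducible.
#'
#' @param genotype_path,annotation_path,covariate_path,phenotype_path Input
#'   files (see [load_genotypes()], [load_covariates()],
#'   [load_phenotypes()]); leave `NULL` when passing objects to [run_all()]
#'   directly.
#' @param out_dir Output directory for all stage artifacts.
#' @param qc A [qc_thresholds()].
#' @param min_gene_size,bin_size Grouping parameters, see [assign_groups()].
#' @param prevalence_min Composite-marker prevalence floor, see
#'   [build_composite_markers()].
#' @param nlambda,lambda_min_ratio Penalty-path specification.
#' @param tree A [tree_spec()].
#' @param significance A [significance_config()].
#' @param construction_replicate Index of the replicate used to build
#'   markers; the first replicate by default, and always excluded from the
#'   evaluation ensemble.
#' @param seed Global seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genotype_path = NULL, annotation_path = NULL,
                       covariate_path = NULL, phenotype_path = NULL,
                       out_dir = "rarelasso_out",
                       qc = qc_thresholds(),
                       min_gene_size = 5L, bin_size = 20L,
                       prevalence_min = 0.05,
                       nlambda = 100L, lambda_min_ratio = 0.001,
                       tree = tree_spec(),
                       significance = significance_config(),
                       construction_replicate = 1L,
                       seed = 1L) {
  structure(list(genotype_path = genotype_path,
                 annotation_path = annotation_path,
                 covariate_path = covariate_path,
                 phenotype_path = phenotype_path,
                 out_dir = out_dir, qc = qc,
                 min_gene_size = as.integer(min_gene_size),
                 bin_size = as.integer(bin_size),
                 prevalence_min = prevalence_min,
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 tree = tree, significance = significance,
                 construction_replicate = as.integer(construction_replicate),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `path` / a [run_config()].
#' @export
write_run_config <- function(config, path) {
  flat <- unclass(config)
  flat$qc <- unclass(flat$qc)
  flat$tree <- unclass(flat$tree)
  flat$significance <- unclass(flat$significance)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(genotype_path = y$genotype_path,
             annotation_path = y$annotation_path,
             covariate_path = y$covariate_path,
             phenotype_path = y$phenotype_path,
             out_dir = y$out_dir,
             qc = do.call(qc_thresholds, y$qc),
             min_gene_size = y$min_gene_size, bin_size = y$bin_size,
             prevalence_min = y$prevalence_min,
             nlambda = y$nlambda, lambda_min_ratio = y$lambda_min_ratio,
             tree = do.call(tree_spec, y$tree),
             significance = do.call(significance_config, y$significance),
             construction_replicate = y$construction_replicate,
             seed = y$seed)
}

#' Run the full collapsing-and-testing pipeline
#'
#' Executes preprocess (MAF + HWE filters) -> group (gene / positional) ->
#' build composite markers on the construction replicate -> classification
#' trees on the remaining replicates -> binomial split-frequency
#' significance. Every intermediate artifact is written under
#' `config$out_dir`, and the log reports the method's own checkpoints:
#' variants removed per filter, groups formed, the number of markers M, the
#' per-tree split summary, S, and the critical value.
#'
#' @param config A [run_config()]. Paths are used unless the data objects
#'   are supplied directly.
#' @param geno,variants,covariates,replicates Optional in-memory inputs
#'   overriding the configured paths.
#' @param verbose Emit progress messages (default TRUE).
#' @return A list of class `run_result`: `qc_report`, `groups`, `markers`
#'   (a [marker_set()]), `usage` (a `usage_counts`), `significance` (a
#'   `significance_result`), `paths` of the written artifacts.
#' @export
run_all <- function(config, geno = NULL, variants = NULL, covariates = NULL,
                    replicates = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  stage <- "load"
  res <- tryCatch({
    if (is.null(geno)) {
      loaded <- load_genotypes(config$genotype_path, config$annotation_path)
      geno <- loaded$geno
      variants <- loaded$variants
    }
    if (is.null(covariates) && !is.null(config$covariate_path))
      covariates <- load_covariates(config$covariate_path, rownames(geno))
    if (is.null(replicates))
      replicates <- load_phenotypes(config$phenotype_path, rownames(geno))
    if (ncol(replicates) < 2L)
      stop("the tree ensemble needs at least one evaluation replicate ",
           "beyond the construction replicate (R >= 2)")
    if (!is.null(covariates)) check_subject_alignment(geno, covariates)
    check_subject_alignment(geno, replicates)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()

    stage <- "preprocess"
    qc <- filter_variants(geno, variants, config$qc)
    rl_log("QC: %d of %d variants kept (%d removed by MAF, %d by HWE)",
           sum(qc$report$kept), nrow(qc$report),
           attr(qc$report, "n_removed_maf"), attr(qc$report, "n_removed_hwe"),
           verbose = verbose)
    paths$qc_report <- file.path(config$out_dir, "qc_report.tsv")
    write.table(qc$report, paths$qc_report, sep = "\t", quote = FALSE,
                row.names = FALSE)

    stage <- "group"
    groups <- assign_groups(qc$variants, config$min_gene_size,
                            config$bin_size)
    rl_log("grouping: %d groups (%d gene, %d positional)",
           length(unique(groups$group_id)),
           length(unique(groups$group_id[groups$kind == "gene"])),
           length(unique(groups$group_id[groups$kind == "positional"])),
           verbose = verbose)
    paths$groups <- file.path(config$out_dir, "groups.tsv")
    write.table(groups, paths$groups, sep = "\t", quote = FALSE,
                row.names = FALSE)

    stage <- "build-markers"
    y_build <- replicates[, config$construction_replicate]
    markers <- build_composite_markers(
      qc$geno, groups, covariates, y_build,
      prevalence_min = config$prevalence_min, nlambda = config$nlambda,
      lambda_min_ratio = config$lambda_min_ratio, verbose = verbose)
    rl_log("markers: M = %d non-rare composite markers", length(markers),
           verbose = verbose)
    paths$markers <- file.path(config$out_dir, "markers.tsv")
    write_marker_set(markers, paths$markers)
    diagnostics <- attr(markers, "diagnostics")
    paths$marker_diagnostics <- file.path(config$out_dir,
                                          "marker_diagnostics.tsv")
    write.table(diagnostics, paths$marker_diagnostics, sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "trees"
    usage <- run_ensemble(markers, covariates, replicates,
                          construction_replicate =
                            config$construction_replicate,
                          spec = config$tree)
    rl_log("trees: %d trees, s_i mean %.2f (sd %.2f), S = %d",
           usage$n_trees, mean(usage$s), stats::sd(usage$s), usage$S,
           verbose = verbose)
    paths$usage <- file.path(config$out_dir, "usage.tsv")
    write.table(data.frame(marker_id = names(usage$counts),
                           count = as.integer(usage$counts),
                           split_count = as.integer(usage$split_counts)),
                paths$usage, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$ensemble <- file.path(config$out_dir, "ensemble.tsv")
    write.table(data.frame(tree = seq_along(usage$s), s_i = usage$s),
                paths$ensemble, sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "test"
    sig <- call_significant(usage, config$significance)
    rl_log("significance: critical value %d at alpha %g / M; %d significant",
           sig$critical_value, config$significance$alpha,
           sum(sig$table$significant), verbose = verbose)
    paths$significance <- file.path(config$out_dir, "significance.tsv")
    write.table(sig$table, paths$significance, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$summary <- file.path(config$out_dir, "summary.json")
    jsonlite::write_json(list(S = sig$S, M = sig$M, alpha = sig$alpha,
                              per_marker_alpha = sig$per_marker_alpha,
                              critical_value = sig$critical_value,
                              n_significant = sum(sig$table$significant),
                              mean_markers_per_tree =
                                mean_markers_per_tree(usage)),
                         paths$summary, auto_unbox = TRUE, digits = NA)
    paths$config <- file.path(config$out_dir, "effective_config.yaml")
    write_run_config(config, paths$config)

    structure(list(qc_report = qc$report, groups = groups, markers = markers,
                   usage = usage, significance = sig, paths = paths),
              class = "run_result")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}
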