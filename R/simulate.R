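#' Configuration for a synthetic case-control cohort
#'
#' Describes a cohort of unrelated subjects with a strongly rare-skewed
#' allele-frequency spectrum, population/age/sex/smoking covariates, a small
#' set of causal genes acting through rare-variant carriers on the logistic
#' (log-odds) scale, and `n_replicates` independent phenotype redraws on
#' fixed genotypes. Defaults follow the structure of the cohort the method
#' was developed on: 697 unrelated subjects in 17 population groups, 200
#' phenotype replicates, and an allele-frequency mixture placing 38.5% of
#' variants below MAF 0.001, 74.0% below 0.01 and 87.2% below 0.05.
#'
#' @param n_subjects Number of subjects (default 697).
#' @param n_populations Number of population groups (default 17).
#' @param n_variants Number of variants (default 5000).
#' @param n_genes Target number of genes (default 250).
#' @param n_chromosomes Number of chromosomes variants are spread over
#'   (default 22).
#' @param maf_spectrum Mixture weights over the MAF strata
#'   (<0.001, 0.001–0.01, 0.01–0.05, >0.05); must sum to 1
#'   (default `c(0.385, 0.355, 0.132, 0.128)`).
#' @param intergenic_rate Fraction of variants left without a gene label
#'   (default 0.2), exercising positional grouping downstream.
#' @param causal_genes List of `list(gene = <index>, beta = <log-odds per
#'   carrier>)`; empty for a null cohort.
#' @param causal_maf_range Optional `c(lo, hi)`: redraw the causal genes'
#'   variant MAFs log-uniformly in this range, controlling the aggregate
#'   carrier prevalence of the causal signal.
#' @param beta0 Baseline log-odds of being a case (default -1).
#' @param beta_age Log-odds per year of age, centered at 50 (default 0.02).
#' @param beta_sex,beta_smoke Log-odds for sex = 1 / smoking = 1
#'   (defaults 0.5, 0.5).
#' @param pop_intercepts Per-population log-odds shifts, length
#'   `n_populations` or a single value recycled (default 0).
#' @param n_replicates Number of phenotype replicates R (default 200).
#' @param seed Integer seed; fixing it makes every output reproducible.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 697L, n_populations = 17L,
                          n_variants = 5000L, n_genes = 250L,
                          n_chromosomes = 22L,
                          maf_spectrum = c(0.385, 0.355, 0.132, 0.128),
                          intergenic_rate = 0.2,
                          causal_genes = list(),
                          causal_maf_range = NULL,
                          beta0 = -1, beta_age = 0.02, beta_sex = 0.5,
                          beta_smoke = 0.5, pop_intercepts = 0,
                          n_replicates = 200L, seed = 1L) {
  stopifnot(n_subjects >= 1L, n_variants >= 1L, n_genes >= 1L,
            n_populations >= 1L, n_replicates >= 1L,
            length(maf_spectrum) == 4L,
            intergenic_rate >= 0, intergenic_rate < 1)
  if (abs(sum(maf_spectrum) - 1) > 1e-8)
    stop("maf_spectrum weights must sum to 1")
  for (cg in causal_genes) {
    if (is.null(cg$gene) || is.null(cg$beta))
      stop("each causal_genes entry needs fields gene (index) and beta")
    if (cg$gene < 1L || cg$gene > n_genes)
      stop("causal gene index ", cg$gene, " outside 1..n_genes")
  }
  pop_intercepts <- rep_len(pop_intercepts, n_populations)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_populations = as.integer(n_populations),
                 n_variants = as.integer(n_variants),
                 n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 maf_spectrum = maf_spectrum,
                 intergenic_rate = intergenic_rate,
                 causal_genes = causal_genes,
                 causal_maf_range = causal_maf_range,
                 beta0 = beta0, beta_age = beta_age, beta_sex = beta_sex,
                 beta_smoke = beta_smoke, pop_intercepts = pop_intercepts,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

MAF_STRATA <- list(c(5e-5, 1e-3), c(1e-3, 1e-2), c(1e-2, 5e-2), c(5e-2, 0.5))

#' Generate a synthetic case-control cohort
#'
#' Genotypes are drawn per variant as Binomial(2, MAF) with the MAF sampled
#' log-uniformly within a stratum chosen from the configured spectrum.
#' Variants are laid out contiguously along `n_chromosomes` chromosomes;
#' genic variants form contiguous gene blocks and a configurable fraction
#' stays intergenic (empty gene label). Each phenotype replicate is an
#' independent Bernoulli draw from
#' `logit^-1(beta0 + population + age + sex + smoking terms +
#' sum_g beta_g * carrier_g)` on the fixed genotypes, where `carrier_g`
#' indicates carrying a minor allele at any variant of causal gene `g`.
#'
#' @param config A [cohort_config()].
#' @return A list with `geno` ([genotype_matrix()], minor-allele polarized),
#'   `variants` ([variant_table()] with sample MAFs), `covariates`
#'   ([covariate_table()]), `replicates` ([phenotype_replicates()]), and
#'   `truth`: `causal_genes` (data.frame gene, beta, carrier_prevalence) and
#'   `causal_variants` (character).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  N <- config$n_subjects
  P <- config$n_variants

  stratum <- sample.int(4L, P, replace = TRUE, prob = config$maf_spectrum)
  lo <- vapply(MAF_STRATA, `[`, numeric(1), 1)[stratum]
  hi <- vapply(MAF_STRATA, `[`, numeric(1), 2)[stratum]
  true_maf <- 10^runif(P, log10(lo), log10(hi))

  # contiguous chromosome blocks with cumulative random inter-variant gaps
  chrom_sizes <- diff(floor(seq(0, P, length.out = config$n_chromosomes + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), chrom_sizes)
  pos <- unlist(lapply(chrom_sizes, function(k)
    cumsum(sample(100:10000, k, replace = TRUE))), use.names = FALSE)

  # gene blocks: contiguous runs of genic variants, never crossing chromosomes
  intergenic <- runif(P) < config$intergenic_rate
  gene <- rep("", P)
  target <- max(1, round(sum(!intergenic) / config$n_genes))
  gene_counter <- 0L
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr & !intergenic)
    if (!length(idx)) next
    n_gene_chr <- max(1L, round(length(idx) / target))
    block <- cut(seq_along(idx), breaks = n_gene_chr, labels = FALSE)
    gene[idx] <- sprintf("G%04d", gene_counter + block)
    gene_counter <- gene_counter + n_gene_chr
  }
  n_genes_actual <- gene_counter
  gene_names <- sprintf("G%04d", seq_len(n_genes_actual))
  for (cg in config$causal_genes)
    if (cg$gene > n_genes_actual)
      stop("causal gene index ", cg$gene, " exceeds the ", n_genes_actual,
           " genes actually formed")

  if (!is.null(config$causal_maf_range)) {
    rng <- config$causal_maf_range
    causal_gene_names <- gene_names[vapply(config$causal_genes,
                                           function(cg) cg$gene, numeric(1))]
    sel <- gene %in% causal_gene_names
    true_maf[sel] <- 10^runif(sum(sel), log10(rng[1]), log10(rng[2]))
  }

  calls <- matrix(rbinom(N * P, 2L, rep(true_maf, each = N)), nrow = N,
                  dimnames = list(sprintf("S%04d", seq_len(N)),
                                  sprintf("V%05d", seq_len(P))))
  pol <- polarize_genotypes(genotype_matrix(calls))
  geno <- pol$geno
  variants <- variant_table(variant_id = colnames(geno), chrom = chrom,
                            pos = pos, gene = gene, maf = unname(pol$maf))

  covariates <- covariate_table(
    subject_id = rownames(geno),
    population = sprintf("pop%02d", sample.int(config$n_populations, N,
                                               replace = TRUE)),
    age = pmin(pmax(round(rnorm(N, 50, 12)), 18), 90),
    sex = rbinom(N, 1, 0.5),
    smoking = rbinom(N, 1, 0.3))

  lp <- config$beta0 +
    config$pop_intercepts[as.integer(factor(covariates$population,
      levels = sprintf("pop%02d", seq_len(config$n_populations))))] +
    config$beta_age * (covariates$age - 50) +
    config$beta_sex * covariates$sex +
    config$beta_smoke * covariates$smoking
  causal_variants <- character(0)
  truth_rows <- list()
  for (cg in config$causal_genes) {
    gname <- gene_names[cg$gene]
    vars <- variants$variant_id[variants$gene == gname]
    carrier <- as.integer(rowSums(
      make_dummies(geno[, vars, drop = FALSE])) > 0)
    lp <- lp + cg$beta * carrier
    causal_variants <- c(causal_variants, vars)
    truth_rows[[length(truth_rows) + 1L]] <-
      data.frame(gene = gname, beta = cg$beta,
                 carrier_prevalence = mean(carrier),
                 stringsAsFactors = FALSE)
  }
  p_case <- 1 / (1 + exp(-lp))

  status <- matrix(0L, N, config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    for (try in seq_len(100L)) {
      col <- rbinom(N, 1L, p_case)
      if (any(col == 1L) && any(col == 0L)) break
    }
    status[, r] <- col
  }
  replicates <- phenotype_replicates(status, subject_ids = rownames(geno),
                                     replicate_labels = paste0(
                                       "rep_", seq_len(config$n_replicates)))

  truth <- list(
    causal_genes = if (length(truth_rows)) do.call(rbind, truth_rows)
      else data.frame(gene = character(0), beta = numeric(0),
                      carrier_prevalence = numeric(0)),
    causal_variants = causal_variants)
  list(geno = geno, variants = variants, covariates = covariates,
       replicates = replicates, truth = truth, config = config)
}
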