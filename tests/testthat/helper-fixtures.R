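# Shared fixtures, built in code at test time.

# tiny cohort for fast end-to-end checks
small_cohort <- function(seed = 1L, n_subjects = 150L, n_variants = 300L,
                         n_genes = 25L, n_replicates = 6L,
                         causal = list()) {
  generate_cohort(cohort_config(
    n_subjects = n_subjects, n_variants = n_variants, n_genes = n_genes,
    n_chromosomes = 2L, n_populations = 3L, n_replicates = n_replicates,
    intergenic_rate = 0.2, causal_genes = causal, seed = seed))
}

random_covariates <- function(n, seed = 1L) {
  withr::with_seed(seed, covariate_table(
    subject_id = sprintf("S%04d", seq_len(n)),
    population = sample(c("popA", "popB", "popC"), n, replace = TRUE),
    age = round(runif(n, 20, 80)),
    sex = rbinom(n, 1, 0.5),
    smoking = rbinom(n, 1, 0.3)))
}

random_marker_set <- function(n_subjects = 8L, n_markers = 3L, seed = 1L) {
  withr::with_seed(seed, {
    markers <- lapply(seq_len(n_markers), function(i) {
      k <- sample(1:4, 1)
      list(marker_id = sprintf("m%03d", i),
           group_id = sprintf("gene:G%02d", i),
           members = sprintf("V%05d", sample.int(99999, k)),
           weights = round(rnorm(k), 6))
    })
    vals <- matrix(rnorm(n_subjects * n_markers),
                   nrow = n_subjects,
                   dimnames = list(sprintf("S%04d", seq_len(n_subjects)),
                                   NULL))
    vals[sample(length(vals), length(vals) %/% 3)] <- 0
    marker_set(markers, vals)
  })
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# 3-subject VCF with one line per supplied genotype string vector
tiny_vcf <- function(site_gts, subjects = c("S1", "S2", "S3"),
                     ids = sprintf("rs%d", seq_along(site_gts))) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", subjects), collapse = "\t"))
  body <- vapply(seq_along(site_gts), function(i)
    paste(c("chr1", 100 * i, ids[i], "A", "G", ".", "PASS", ".", "GT",
            site_gts[[i]]), collapse = "\t"), character(1))
  write_lines_tmp(c(header, body), ".vcf")
}

# independent Hardy-Weinberg exact-test oracle: enumerate every heterozygote
# count compatible with the fixed allele totals, with probabilities from
# binomial coefficients (choose), and sum those no more likely than observed
hwe_oracle <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  na <- 2 * min(n_hom_major, n_hom_minor) + n_het
  if (na == 0) return(1)
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  prob <- vapply(hets, function(h) {
    hom_min <- (na - h) / 2
    choose(n, hom_min) * choose(n - hom_min, h) * 2^h
  }, numeric(1))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# exhaustive binomial-quantile oracle by CDF summation
binom_crit_oracle <- function(S, M, alpha) {
  if (S == 0) return(0L)
  target <- 1 - alpha / M
  cdf <- cumsum(dbinom(0:S, S, 1 / M))
  as.integer(min(which(cdf >= target)) - 1L)
}

# exhaustive weighted-Gini search for the best single split of a root node
best_gini_split <- function(features, y) {
  gini <- function(labels) {
    p <- mean(labels)
    2 * p * (1 - p)
  }
  n <- length(y)
  best <- list(gain = -Inf, feature = NA_character_)
  for (f in colnames(features)) {
    x <- features[[f]]
    cuts <- sort(unique(x))
    if (length(cuts) < 2) next
    for (c in cuts[-length(cuts)]) {
      left <- y[x <= c]
      right <- y[x > c]
      gain <- gini(y) - (length(left) / n) * gini(left) -
        (length(right) / n) * gini(right)
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = f, cut = c)
      }
    }
  }
  best
}
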