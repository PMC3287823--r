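#' Variant QC thresholds
#'
#' Boundary conventions follow the usual strict inequalities: variants with
#' MAF *greater than* `maf_max` are excluded (MAF equal to the threshold is
#' retained), and variants whose exact Hardy-Weinberg p-value is *below*
#' `hwe_alpha` fail (a p-value equal to the threshold passes).
#'
#' @param maf_max Maximum minor allele frequency retained (default 0.05).
#' @param hwe_alpha Hardy-Weinberg exact-test significance level below which
#'   a variant is excluded (default 1e-4).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_max = 0.05, hwe_alpha = 1e-4) {
  stopifnot(maf_max > 0, maf_max <= 0.5, hwe_alpha > 0, hwe_alpha < 1)
  structure(list(maf_max = maf_max, hwe_alpha = hwe_alpha),
            class = "qc_thresholds")
}

#' Minor allele frequency of one variant
#'
#' @param calls Integer vector of genotype calls in \{0, 1, 2\}; `NA` entries
#'   (missing calls) are excluded from the denominator.
#' @return `min(p, 1 - p)` where `p` is the counted-allele frequency over
#'   non-missing subjects.
#' @export
compute_maf <- function(calls) {
  n_obs <- sum(!is.na(calls))
  if (n_obs == 0L) stop("cannot compute MAF: all calls missing")
  p <- sum(calls, na.rm = TRUE) / (2 * n_obs)
  min(p, 1 - p)
}

#' Hardy-Weinberg exact test p-value
#'
#' Exact conditional test on genotype counts: given the subject total and the
#' minor-allele total, the p-value sums the probabilities of every
#' heterozygote count whose conditional probability does not exceed that of
#' the observed count. Appropriate for rare variants, where the chi-square
#' approximation breaks down. Symmetric in the two homozygote counts.
#'
#' @param n_hom_major,n_het,n_hom_minor Nonnegative genotype counts; their
#'   sum must be at least 1.
#' @return A p-value in (0, 1]; monomorphic variants give 1.
#' @export
hwe_exact_pvalue <- function(n_hom_major, n_het, n_hom_minor) {
  stopifnot(n_hom_major >= 0, n_het >= 0, n_hom_minor >= 0)
  n <- n_hom_major + n_het + n_hom_minor
  if (n < 1L) stop("at least one genotyped subject is required")
  n_a <- 2L * min(n_hom_major, n_hom_minor) + n_het  # minor-allele count
  if (n_a == 0L) return(1)
  # heterozygote counts compatible with fixed allele totals share n_a's parity
  hets <- seq.int(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
  logp <- hwe_het_logprob(hets, n, n_a)
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)
  p_obs <- p_all[match(n_het, hets)]
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-12)]))
}

# log conditional probability of a heterozygote count given n subjects and
# n_a minor alleles: P(het) = n! / (hom_maj! het! hom_min!) * 2^het /
#                             [ (2n)! / (n_a! n_A!) ]
hwe_het_logprob <- function(het, n, n_a) {
  hom_min <- (n_a - het) / 2
  hom_maj <- n - het - hom_min
  lgamma(n + 1) - lgamma(hom_maj + 1) - lgamma(het + 1) -
    lgamma(hom_min + 1) + het * log(2) +
    lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
}

#' Filter variants on MAF and Hardy-Weinberg equilibrium
#'
#' Removes common variants (`maf > maf_max`) and Hardy-Weinberg failures
#' (`hwe_p < hwe_alpha`), mirroring the standard rare-variant preprocessing:
#' exclude all SNPs with MAF > 0.05 and all SNPs failing the HWE exact test
#' at p < 1e-4. HWE is evaluated on the pooled sample, since genotypes are
#' fixed across phenotype replicates.
#'
#' @param geno A [genotype_matrix()] (minor-allele counts).
#' @param variants The matching [variant_table()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with `geno` and `variants` restricted to the surviving
#'   variants, and `report`: a data.frame (variant_id, maf, hwe_p, kept,
#'   reason) plus attributes `n_removed_maf` and `n_removed_hwe`.
#' @export
filter_variants <- function(geno, variants, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"),
            identical(colnames(geno), variants$variant_id))
  maf <- apply(geno, 2, compute_maf)
  hwe_p <- vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    hwe_exact_pvalue(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                     sum(g == 2L, na.rm = TRUE))
  }, numeric(1))
  fail_maf <- maf > thresholds$maf_max
  fail_hwe <- hwe_p < thresholds$hwe_alpha
  kept <- !fail_maf & !fail_hwe
  reason <- rep("", length(kept))
  reason[fail_maf] <- "maf"
  reason[fail_hwe] <- ifelse(fail_maf[fail_hwe], "maf;hwe", "hwe")
  report <- data.frame(variant_id = variants$variant_id, maf = maf,
                       hwe_p = hwe_p, kept = kept, reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  attr(report, "n_removed_maf") <- sum(fail_maf)
  attr(report, "n_removed_hwe") <- sum(fail_hwe & !fail_maf)
  if (!any(kept))
    warning("no variant survived QC")
  vt <- variants[kept, , drop = FALSE]
  vt$maf <- maf[kept]
  rownames(vt) <- NULL
  g <- if (any(kept)) genotype_matrix(unclass(geno)[, kept, drop = FALSE])
       else unclass(geno)[, kept, drop = FALSE]
  list(geno = g, variants = vt, report = report)
}
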