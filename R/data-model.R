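#' Construct a genotype matrix
#'
#' The package's central genotype container: an `N x P` integer matrix of
#' minor-allele counts (0, 1 or 2; `NA` marks a missing call) with unique
#' subject identifiers on the rows and variant identifiers on the columns.
#'
#' @param calls Integer matrix, subjects in rows and variants in columns.
#'   Non-missing entries must lie in \{0, 1, 2\}.
#' @param subject_ids Character vector of unique subject identifiers, one per
#'   row of `calls`.
#' @param variant_ids Character vector of unique variant identifiers, one per
#'   column of `calls`.
#' @return An object of class `genotype_matrix` (an integer matrix with
#'   dimnames set to the subject and variant identifiers).
#' @seealso [variant_table()], [polarize_genotypes()]
#' @export
genotype_matrix <- function(calls, subject_ids = rownames(calls),
                            variant_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) < 1L || ncol(calls) < 1L)
    stop("genotype matrix must have at least one subject and one variant")
  if (is.null(subject_ids) || length(subject_ids) != nrow(calls))
    stop("subject_ids must give one identifier per row")
  if (anyDuplicated(subject_ids))
    stop("subject_ids must be unique")
  if (is.null(variant_ids) || length(variant_ids) != ncol(calls))
    stop("variant_ids must give one identifier per column")
  if (anyDuplicated(variant_ids))
    stop("variant_ids must be unique")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype calls must be 0, 1, 2 or NA (missing)")
  dimnames(calls) <- list(as.character(subject_ids), as.character(variant_ids))
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d variants (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Construct a variant annotation table
#'
#' Per-variant metadata: chromosome, 1-based base-pair position, gene label
#' (empty string for intergenic variants) and minor allele frequency.
#'
#' @param variant_id Character, unique variant identifiers.
#' @param chrom Character, chromosome labels.
#' @param pos Integer, 1-based positions (>= 1).
#' @param gene Character, gene labels; `""` means no gene annotation.
#' @param maf Numeric in \[0, 0.5\], minor allele frequency; may be `NA`
#'   before it has been computed from calls.
#' @return A `data.frame` of class `variant_table`.
#' @export
variant_table <- function(variant_id, chrom, pos, gene = "", maf = NA_real_) {
  vt <- data.frame(variant_id = as.character(variant_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   gene = as.character(gene),
                   maf = as.numeric(maf),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(vt$variant_id)) stop("variant_id must be unique")
  if (any(vt$pos < 1L)) stop("positions are 1-based and must be >= 1")
  ok <- is.na(vt$maf) | (vt$maf >= 0 & vt$maf <= 0.5)
  if (!all(ok))
    stop("maf must lie in [0, 0.5] after minor-allele polarization")
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Construct a covariate table
#'
#' One row per subject: population (categorical), age in years, sex and
#' smoking status as 0/1 indicators.
#'
#' @param subject_id Character, unique subject identifiers.
#' @param population Factor or character, population / race-ethnicity group.
#' @param age Numeric, age in years.
#' @param sex Integer 0/1.
#' @param smoking Integer 0/1.
#' @return A `data.frame` of class `covariate_table`; `population` is stored
#'   as a factor with explicit levels.
#' @export
covariate_table <- function(subject_id, population, age, sex, smoking) {
  ct <- data.frame(subject_id = as.character(subject_id),
                   population = factor(population),
                   age = as.numeric(age),
                   sex = as.integer(sex),
                   smoking = as.integer(smoking),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ct$subject_id)) stop("subject_id must be unique")
  if (!all(ct$sex %in% 0:1) || !all(ct$smoking %in% 0:1))
    stop("sex and smoking must be 0/1 indicators")
  class(ct) <- c("covariate_table", "data.frame")
  ct
}

#' Construct phenotype replicates
#'
#' An `N x R` matrix of case/control indicators: independent phenotype
#' redraws on fixed genotypes. Every replicate must contain at least one
#' case and one control.
#'
#' @param status 0/1 matrix, subjects in rows and replicates in columns.
#' @param subject_ids Character vector of subject identifiers.
#' @param replicate_labels Optional character vector of replicate labels;
#'   defaults to `rep_1 ... rep_R`.
#' @return An integer matrix of class `phenotype_replicates`.
#' @export
phenotype_replicates <- function(status, subject_ids = rownames(status),
                                 replicate_labels = colnames(status)) {
  status <- as.matrix(status)
  storage.mode(status) <- "integer"
  if (ncol(status) < 1L) stop("at least one phenotype replicate is required")
  if (!all(status %in% 0:1))
    stop("phenotype values must be 0 (control) or 1 (case)")
  if (is.null(subject_ids) || length(subject_ids) != nrow(status))
    stop("subject_ids must give one identifier per row")
  cases <- colSums(status)
  bad <- which(cases == 0L | cases == nrow(status))
  if (length(bad))
    stop("replicate(s) ", paste(bad, collapse = ", "),
         " lack either a case or a control")
  if (is.null(replicate_labels))
    replicate_labels <- paste0("rep_", seq_len(ncol(status)))
  dimnames(status) <- list(as.character(subject_ids),
                           as.character(replicate_labels))
  class(status) <- c("phenotype_replicates", class(status))
  status
}

#' Construct a set of composite markers
#'
#' A composite marker is a weighted linear combination of carrier indicators
#' for the variants selected within one group; its per-subject value is
#' `v_j = sum_k w_k d_jk`. The set may be empty.
#'
#' @param markers A list; each element is a list with fields `marker_id`,
#'   `group_id`, `members` (character vector of variant ids) and `weights`
#'   (numeric, same length, at least one nonzero).
#' @param values Numeric `N x M` matrix of per-subject marker values with
#'   subject ids as row names and marker ids as column names; for `M = 0` a
#'   zero-column matrix with row names.
#' @return An object of class `marker_set` with elements `markers` and
#'   `values`.
#' @export
marker_set <- function(markers, values) {
  values <- as.matrix(values)
  if (length(markers) != ncol(values))
    stop("values must have one column per marker")
  ids <- vapply(markers, function(m) m$marker_id, character(1))
  if (anyDuplicated(ids)) stop("marker_id must be unique")
  for (m in markers) {
    if (length(m$members) < 1L || length(m$members) != length(m$weights))
      stop("each marker needs members with one weight each")
    if (all(m$weights == 0))
      stop("marker '", m$marker_id, "' has no nonzero weight")
  }
  if (length(markers)) colnames(values) <- ids
  if (is.null(rownames(values)))
    stop("values must carry subject ids as row names")
  out <- list(markers = markers, values = values)
  class(out) <- "marker_set"
  out
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d composite markers over %d subjects\n",
              length(x$markers), nrow(x$values)))
  invisible(x)
}

#' @export
length.marker_set <- function(x) length(x$markers)

#' Marker carrier prevalence
#'
#' Fraction of subjects with a nonzero composite-marker value, per marker.
#'
#' @param ms A [marker_set()].
#' @return Named numeric vector of prevalences.
#' @export
marker_prevalence <- function(ms) {
  if (length(ms$markers) == 0L) return(setNames(numeric(0), character(0)))
  colMeans(ms$values != 0)
}

check_subject_alignment <- function(geno, ...) {
  ids <- rownames(geno)
  for (obj in list(...)) {
    other <- if (is.data.frame(obj)) obj$subject_id else rownames(obj)
    if (!identical(as.character(other), as.character(ids))) {
      miss <- setdiff(ids, other)
      extra <- setdiff(other, ids)
      stop("subject ids are not aligned",
           if (length(miss)) paste0("; missing: ",
                                    paste(head(miss, 5), collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ",
                                     paste(head(extra, 5), collapse = ", ")))
    }
  }
  invisible(TRUE)
}
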