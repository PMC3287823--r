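#' Polarize genotype calls to minor-allele counts
#'
#' Flips any variant whose counted allele has sample frequency above 0.5 so
#' that calls count the minor allele in the loaded sample. Idempotent.
#'
#' @param geno A [genotype_matrix()].
#' @return A list with `geno` (polarized [genotype_matrix()]), `maf`
#'   (named per-variant minor allele frequency) and `flipped` (logical,
#'   which variants were recoded).
#' @export
polarize_genotypes <- function(geno) {
  n_obs <- colSums(!is.na(geno))
  if (any(n_obs == 0L))
    stop("variant(s) with all calls missing: ",
         paste(head(colnames(geno)[n_obs == 0L], 5), collapse = ", "))
  p <- colSums(geno, na.rm = TRUE) / (2 * n_obs)
  flip <- p > 0.5
  if (any(flip)) {
    flipped <- 2L - geno[, flip, drop = FALSE]
    geno[, flip] <- flipped
    p[flip] <- 1 - p[flip]
  }
  list(geno = genotype_matrix(unclass(geno)), maf = p, flipped = flip)
}

parse_vcf_gt <- function(gt) {
  # strip any FORMAT payload beyond GT, split on / or |
  gt <- sub(":.*$", "", gt)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  to_int <- function(a) c(0L, 1L)[match(a, c("0", "1"))]
  calls <- to_int(a1) + to_int(a2)
  calls[is.na(gt) | gt == "." ] <- NA_integer_
  calls
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-site files come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic <- !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    alt != "."
  if (!all(biallelic)) {
    warning(sum(!biallelic), " non-bi-allelic or non-SNP site(s) dropped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  calls <- apply(gt, 2, parse_vcf_gt)
  calls <- matrix(as.integer(calls), nrow = nrow(gt),
                  dimnames = list(ids, colnames(gt)))
  list(calls = t(calls),
       chrom = as.character(fix[, "CHROM"]),
       pos = as.integer(fix[, "POS"]),
       variant_id = ids)
}

read_ped_map_genotypes <- function(ped_path, map_path) {
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L)
    stop("malformed .map file (need chrom, id, cM, pos): ", map_path)
  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  p <- nrow(map)
  if (ncol(ped) != 6L + 2L * p)
    stop("malformed .ped file: expected ", 6L + 2L * p,
         " columns for ", p, " variants, found ", ncol(ped))
  subject_ids <- ped[[2]]
  calls <- matrix(NA_integer_, nrow = nrow(ped), ncol = p)
  for (j in seq_len(p)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    alleles <- c(a1, a2)
    alleles <- alleles[alleles != "0"]
    lev <- sort(unique(alleles))
    if (length(lev) > 2L)
      stop("variant ", map[[2]][j], " has more than two alleles")
    # count the lexicographically-later allele; polarization fixes orientation
    target <- lev[length(lev)]
    g <- (a1 == target) + (a2 == target)
    g[a1 == "0" | a2 == "0"] <- NA_integer_
    calls[, j] <- as.integer(g)
  }
  dimnames(calls) <- list(subject_ids, map[[2]])
  list(calls = calls, chrom = as.character(map[[1]]),
       pos = as.integer(map[[4]]), variant_id = map[[2]])
}

#' Load genotypes and variant annotation
#'
#' Reads genotypes from a VCF (v4.x, bi-allelic SNPs only) or from PLINK-style
#' `.ped`/`.map` text files, joins a variant-to-gene annotation table, and
#' polarizes calls so that the counted allele is the minor allele in the
#' loaded sample. Half-calls and `./.` become missing (`NA`); the site is
#' retained.
#'
#' @param path Path to a `.vcf` file or to a `.ped` file (a `.map` file with
#'   the same stem must sit next to it).
#' @param annotation Path to a tab-separated annotation table with columns
#'   `variant_id`, `chrom`, `pos`, `gene`. Variants absent from the table
#'   keep their genotype-file coordinates and get an empty gene label (with
#'   a warning).
#' @return A list with `geno` (a [genotype_matrix()]) and `variants`
#'   (a [variant_table()] with `maf` populated from the sample).
#' @export
load_genotypes <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    raw <- read_vcf_genotypes(path)
  } else if (grepl("\\.ped$", path, ignore.case = TRUE)) {
    map_path <- sub("\\.ped$", ".map", path, ignore.case = TRUE)
    if (!file.exists(map_path)) stop(".map file not found: ", map_path)
    raw <- read_ped_map_genotypes(path, map_path)
  } else {
    stop("unrecognized genotype format (expect .vcf[.gz] or .ped): ", path)
  }
  geno <- genotype_matrix(raw$calls)
  pol <- polarize_genotypes(geno)
  gene <- rep("", length(raw$variant_id))
  chrom <- raw$chrom
  pos <- raw$pos
  if (!is.null(annotation)) {
    ann <- read.table(annotation, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = "character",
                      quote = "")
    need <- c("variant_id", "chrom", "pos", "gene")
    if (!all(need %in% names(ann)))
      stop("annotation must have columns: ", paste(need, collapse = ", "))
    idx <- match(raw$variant_id, ann$variant_id)
    hit <- !is.na(idx)
    if (any(!hit))
      warning(sum(!hit), " variant(s) missing from annotation; ",
              "gene label set to empty")
    gene[hit] <- ann$gene[idx[hit]]
    chrom[hit] <- ann$chrom[idx[hit]]
    pos[hit] <- as.integer(ann$pos[idx[hit]])
  }
  variants <- variant_table(variant_id = raw$variant_id, chrom = chrom,
                            pos = pos, gene = gene,
                            maf = unname(pol$maf[raw$variant_id]))
  miss_rate <- colMeans(is.na(pol$geno))
  noisy <- names(miss_rate)[miss_rate > 0.05]
  if (length(noisy))
    message(length(noisy), " variant(s) with >5% missing calls: ",
            paste(head(noisy, 5), collapse = ", "),
            if (length(noisy) > 5) ", ...")
  list(geno = pol$geno, variants = variants)
}

#' Load phenotype replicates from a delimited table
#'
#' Expects a header row, a `subject_id` column and one 0/1 column per
#' replicate.
#'
#' @param path Path to a tab- or comma-separated file.
#' @param subject_ids Optional character vector; when given, the table's
#'   subjects must match it exactly (any order) and rows are reordered to it.
#' @return A [phenotype_replicates()] matrix.
#' @export
load_phenotypes <- function(path, subject_ids = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(tab))
    stop("phenotype table needs a subject_id column")
  ids <- as.character(tab$subject_id)
  mat <- as.matrix(tab[, setdiff(names(tab), "subject_id"), drop = FALSE])
  if (!all(mat %in% 0:1))
    stop("phenotype values must be 0/1; offending value(s): ",
         paste(head(unique(mat[!mat %in% 0:1])), collapse = ", "))
  rownames(mat) <- ids
  if (!is.null(subject_ids)) {
    miss <- setdiff(subject_ids, ids)
    extra <- setdiff(ids, subject_ids)
    if (length(miss) || length(extra))
      stop("phenotype subjects do not match genotype subjects",
           if (length(miss)) paste0("; missing: ",
                                    paste(head(miss, 5), collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ",
                                     paste(head(extra, 5), collapse = ", ")))
    mat <- mat[as.character(subject_ids), , drop = FALSE]
  }
  phenotype_replicates(mat)
}

#' Load a covariate table from a delimited file
#'
#' @param path Path to a CSV/TSV with columns `subject_id`, `population`,
#'   `age`, `sex`, `smoking`.
#' @param subject_ids Optional vector to align against (see
#'   [load_phenotypes()]).
#' @return A [covariate_table()].
#' @export
load_covariates <- function(path, subject_ids = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject_id", "population", "age", "sex", "smoking")
  if (!all(need %in% names(tab)))
    stop("covariate table needs columns: ", paste(need, collapse = ", "))
  if (!is.null(subject_ids)) {
    if (!setequal(tab$subject_id, subject_ids))
      stop("covariate subjects do not match genotype subjects")
    tab <- tab[match(subject_ids, tab$subject_id), ]
  }
  covariate_table(tab$subject_id, tab$population, tab$age, tab$sex,
                  tab$smoking)
}

MARKER_SET_SCHEMA <- 1L

#' Write a marker set to its TSV + JSON-header file
#'
#' The file starts with a single `#` comment line carrying a JSON object
#' (schema version plus per-marker group, members and weights, in order),
#' followed by a tab-separated table of per-subject marker values. Numeric
#' values are written with 17 significant digits so a write/read round trip
#' is bit-exact.
#'
#' @param ms A [marker_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_set <- function(ms, path) {
  stopifnot(inherits(ms, "marker_set"))
  header <- list(
    schema = MARKER_SET_SCHEMA,
    markers = lapply(ms$markers, function(m)
      list(marker_id = m$marker_id, group_id = m$group_id,
           members = as.list(m$members),
           weights = as.list(sprintf("%.17g", m$weights)))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(header, auto_unbox = TRUE)), con)
  vals <- ms$values
  df <- data.frame(subject_id = rownames(vals), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(vals))) df[[colnames(vals)[j]]] <-
      sprintf("%.17g", vals[, j])
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker set written by [write_marker_set()]
#'
#' @param path Path to a marker-set file.
#' @return A [marker_set()]; `read(write(m))` reproduces `m` exactly,
#'   including weight order.
#' @export
read_marker_set <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("not a marker-set file (missing JSON header line): ", path)
  header <- jsonlite::fromJSON(sub("^#", "", lines[1]), simplifyVector = FALSE)
  if (is.null(header$schema) || header$schema != MARKER_SET_SCHEMA)
    stop("unknown marker-set schema version: ",
         if (is.null(header$schema)) "<none>" else header$schema)
  markers <- lapply(header$markers, function(m)
    list(marker_id = m$marker_id, group_id = m$group_id,
         members = as.character(unlist(m$members)),
         weights = as.numeric(unlist(m$weights))))
  ids <- vapply(markers, function(m) m$marker_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate marker_id in file: ", path)
  body <- read.table(text = lines[-1], header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, colClasses = "character",
                     check.names = FALSE)
  vals <- matrix(0, nrow = nrow(body), ncol = length(markers),
                 dimnames = list(body$subject_id, ids))
  for (id in ids) vals[, id] <- as.numeric(body[[id]])
  marker_set(markers, vals)
}

#' Write phenotype replicates or a covariate table to TSV
#' @param x A [phenotype_replicates()] matrix or [covariate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(x, path) {
  if (inherits(x, "phenotype_replicates")) {
    df <- data.frame(subject_id = rownames(x), as.data.frame(unclass(x)),
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix and variant table as a VCF
#'
#' Emits a minimal VCF v4.2 with GT-only genotype columns, suitable for
#' re-loading with [load_genotypes()]. Missing calls become `./.`.
#'
#' @param geno A [genotype_matrix()] (minor-allele counts).
#' @param variants The matching [variant_table()].
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, variants, path) {
  stopifnot(identical(colnames(geno), variants$variant_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno)), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(variants$chrom[j], variants$pos[j],
                       variants$variant_id[j], "A", "T", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the variant annotation table as TSV
#' @param variants A [variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(variants, path) {
  write.table(variants[, c("variant_id", "chrom", "pos", "gene")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
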