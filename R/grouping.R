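#' Partition rare variants into collapsing groups
#'
#' Genes holding at least `min_gene_size` surviving variants become gene
#' groups. All remaining variants — those in smaller genes together with the
#' unannotated (intergenic) ones — are pooled per chromosome, sorted by
#' position, and chunked into consecutive positional bins of `bin_size`
#' variants; a trailing bin smaller than `bin_size / 2` is merged into its
#' neighbour. The result is an exhaustive, disjoint partition of the input
#' variants, invariant to input row order.
#'
#' @param variants A [variant_table()] of QC-surviving variants.
#' @param min_gene_size Minimum number of variants for a gene to form its own
#'   group (default 5).
#' @param bin_size Target positional-bin size in variants (default 20).
#' @return A data.frame of class `group_assignment` with columns `group_id`,
#'   `kind` (`"gene"` or `"positional"`), `chrom`, `variant_id`.
#' @export
assign_groups <- function(variants, min_gene_size = 5L, bin_size = 20L) {
  stopifnot(min_gene_size >= 1L, bin_size >= 2L)
  if (any(is.na(variants$chrom) | variants$chrom == ""))
    stop("variant(s) with unknown chromosome: ",
         paste(head(variants$variant_id[is.na(variants$chrom) |
                                          variants$chrom == ""], 5),
               collapse = ", "))
  # canonical order makes the partition independent of input row order
  variants <- variants[order(variants$chrom, variants$pos,
                             variants$variant_id), , drop = FALSE]
  gene <- variants$gene
  gene[is.na(gene)] <- ""
  counts <- table(gene[gene != ""])
  big_genes <- names(counts)[counts >= min_gene_size]
  out <- list()
  for (g in sort(big_genes)) {
    sel <- variants[gene == g, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      group_id = paste0("gene:", g), kind = "gene",
      chrom = sel$chrom, variant_id = sel$variant_id,
      stringsAsFactors = FALSE)
  }
  leftover <- variants[!(gene %in% big_genes), , drop = FALSE]
  for (chr in unique(leftover$chrom)) {
    sel <- leftover[leftover$chrom == chr, , drop = FALSE]
    n <- nrow(sel)
    starts <- seq(1L, n, by = bin_size)
    sizes <- diff(c(starts, n + 1L))
    if (length(sizes) > 1L && sizes[length(sizes)] < bin_size / 2) {
      sizes[length(sizes) - 1L] <- sizes[length(sizes) - 1L] +
        sizes[length(sizes)]
      sizes <- sizes[-length(sizes)]
    }
    bin <- rep(seq_along(sizes), sizes)
    out[[length(out) + 1L]] <- data.frame(
      group_id = paste0("pos:", chr, ":", bin), kind = "positional",
      chrom = chr, variant_id = sel$variant_id, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(stringsAsFactors = FALSE)))
  if (is.null(res))
    res <- data.frame(group_id = character(0), kind = character(0),
                      chrom = character(0), variant_id = character(0),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("group_assignment", "data.frame")
  res
}

#' Split a group assignment into per-group variant-id lists
#' @param groups A `group_assignment` from [assign_groups()].
#' @return Named list mapping group_id to its member variant ids, in
#'   positional order.
#' @export
group_members <- function(groups) {
  split(groups$variant_id, groups$group_id)[unique(groups$group_id)]
}
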