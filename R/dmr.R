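#' Filter DMRs by significance
#'
#' Keeps differentially methylated regions with q-value strictly below
#' \code{alpha} (default 0.05), the conventional cutoff for calling a DMR
#' significant.
#'
#' @param dmrs data.frame with at least a \code{qvalue} column (see
#'   \code{\link{read_dmr_table}}).
#' @param alpha Significance threshold; rows with \code{qvalue < alpha} are
#'   kept.
#' @return The filtered data.frame.
#' @export
filter_significant <- function(dmrs, alpha = 0.05) {
  if (!"qvalue" %in% names(dmrs)) {
    stop("DMR table has no 'qvalue' column")
  }
  out <- dmrs[!is.na(dmrs$qvalue) & dmrs$qvalue < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap significant DMRs with gene annotations
#'
#' Reports every gene sharing at least one base pair with a significant DMR,
#' using 1-based closed intervals on both sides (so regions \code{[100,150]}
#' and \code{[150,300]} overlap by exactly 1 bp). Gene strand is ignored:
#' only coordinates matter. The summary counts, per methylation context, the
#' number of DMRs and the number of distinct genes overlapping them, plus a
#' total distinct gene count in which a gene hit in several contexts is
#' counted once.
#'
#' @param dmrs Significant DMR table (\code{chrom}, \code{start}, \code{end},
#'   optionally \code{context}); apply \code{\link{filter_significant}}
#'   first, or pass \code{alpha} to filter here.
#' @param genes Gene table (\code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}) as from \code{\link{read_gene_annotation}}.
#' @param alpha Optional significance threshold applied to \code{dmrs} before
#'   overlapping (default \code{NULL}: use the table as given).
#' @return List with \code{hits} (one row per gene-DMR pair: gene_id, chrom,
#'   dmr_start, dmr_end, context), \code{genes} (distinct gene ids hit) and
#'   \code{summary} (per-context n_dmrs, n_genes, plus a "total" row).
#' @examples
#' dmrs <- data.frame(chrom = "chr1", start = 100, end = 150,
#'                    qvalue = 0.01, context = "CG")
#' genes <- data.frame(gene_id = "g1", chrom = "chr1",
#'                     start = 150, end = 300, strand = "+")
#' overlap_genes(dmrs, genes)$genes
#' @export
overlap_genes <- function(dmrs, genes, alpha = NULL) {
  if (!is.null(alpha)) dmrs <- filter_significant(dmrs, alpha)
  if (!"context" %in% names(dmrs)) dmrs$context <- NA_character_
  if (nrow(dmrs) == 0 || nrow(genes) == 0) {
    hits <- data.frame(gene_id = character(0), chrom = character(0),
                       dmr_start = integer(0), dmr_end = integer(0),
                       context = character(0), stringsAsFactors = FALSE)
  } else {
    gr_d <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(dmrs$start, dmrs$end))
    gr_g <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(gr_d, gr_g, minoverlap = 1L,
                                      ignore.strand = TRUE)
    hits <- data.frame(
      gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
      chrom = dmrs$chrom[S4Vectors::queryHits(ov)],
      dmr_start = dmrs$start[S4Vectors::queryHits(ov)],
      dmr_end = dmrs$end[S4Vectors::queryHits(ov)],
      context = dmrs$context[S4Vectors::queryHits(ov)],
      stringsAsFactors = FALSE
    )
  }
  contexts <- unique(dmrs$context)
  summ <- do.call(rbind, lapply(contexts, function(cx) {
    sel_d <- if (is.na(cx)) is.na(dmrs$context) else
      !is.na(dmrs$context) & dmrs$context == cx
    sel_h <- if (is.na(cx)) is.na(hits$context) else
      !is.na(hits$context) & hits$context == cx
    data.frame(context = cx, n_dmrs = sum(sel_d),
               n_genes = length(unique(hits$gene_id[sel_h])),
               stringsAsFactors = FALSE)
  }))
  total <- data.frame(context = "total", n_dmrs = nrow(dmrs),
                      n_genes = length(unique(hits$gene_id)),
                      stringsAsFactors = FALSE)
  list(hits = hits, genes = unique(hits$gene_id),
       summary = rbind(summ, total))
}
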