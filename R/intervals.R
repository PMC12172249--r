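#' Genomic-context classification of insertion points
#'
#' Intervals are supplied 0-based half-open (`[start, end)`) with feature
#' labels; locus positions are 1-based VCF insertion points. When a position
#' falls in several features the precedence is
#' exon > utr5 > utr3 > intron > intergenic; a bare gene body counts as
#' intronic. An unsorted interval table is normalized internally.
#'
#' @param loci `l1_loci` table.
#' @param gene_intervals data.frame with columns `chrom`, `start`, `end`,
#'   `feature` (one of exon, utr5, utr3, intron, gene_body).
#' @return the locus table with `genomic_context` filled in.
#' @export
classify_genomic_context <- function(loci, gene_intervals) {
  feat_rank <- c(exon = 1, utr5 = 2, utr3 = 3, intron = 4, gene_body = 4)
  if (!all(gene_intervals$feature %in% names(feat_rank)))
    stop("unknown feature labels in gene_intervals", call. = FALSE)
  hits <- interval_hits(loci, gene_intervals)
  ctx <- rep("intergenic", nrow(loci))
  if (length(hits$locus_idx)) {
    rank <- feat_rank[gene_intervals$feature[hits$interval_idx]]
    best <- tapply(rank, hits$locus_idx, min)
    label <- c("exonic", "utr5", "utr3", "intronic")[best]
    ctx[as.integer(names(best))] <- label
  }
  loci$genomic_context <- ctx
  loci
}

#' All locus-gene overlaps
#'
#' Standard interval overlap of insertion points against gene intervals
#' (e.g. a disease-gene list); returns every overlapping pair.
#'
#' @param loci `l1_loci` table.
#' @param gene_intervals data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param gene_names character vector parallel to `gene_intervals` rows.
#' @return data.frame with columns `locus_id`, `gene` (zero rows if none).
#' @export
intersect_with_gene_list <- function(loci, gene_intervals, gene_names) {
  stopifnot(length(gene_names) == nrow(gene_intervals))
  hits <- interval_hits(loci, gene_intervals)
  data.frame(locus_id = loci$locus_id[hits$locus_idx],
             gene = gene_names[hits$interval_idx],
             stringsAsFactors = FALSE)
}

# overlap engine: 1-based point queries vs 0-based half-open intervals
interval_hits <- function(loci, intervals) {
  if (nrow(intervals) == 0 || nrow(loci) == 0)
    return(list(locus_idx = integer(), interval_idx = integer()))
  subj <- GenomicRanges::GRanges(
    normalize_chrom(intervals$chrom),
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
  qry <- GenomicRanges::GRanges(
    normalize_chrom(loci$chrom),
    IRanges::IRanges(start = loci$pos, width = 1L)
  )
  ov <- GenomicRanges::findOverlaps(qry, subj)
  list(locus_idx = S4Vectors::queryHits(ov),
       interval_idx = S4Vectors::subjectHits(ov))
}
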