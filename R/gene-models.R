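#' Strand-aware gene endpoints
#'
#' The transcription start site (TSS) is the 5' end of the gene span and the
#' transcription termination site (TTS) its 3' end, both as 0-based genomic
#' positions: on the `+` strand TSS = `start` and TTS = `end - 1`; on the `-`
#' strand TSS = `end - 1` and TTS = `start`.
#'
#' @param genes A `gene_models` tibble.
#' @return Integer vector of positions, one per gene.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' @rdname gene_tss
#' @export
gene_tts <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1L, genes$start)
}

#' Intron intervals of one gene
#'
#' Introns are the per-base complement of the exon union within the gene span,
#' so `exons + introns` tile the span exactly and never overlap.
#'
#' @param gene One row of a `gene_models` tibble.
#' @return Tibble with `start`/`end` columns (0-based half-open), possibly
#'   empty.
#' @export
gene_introns <- function(gene) {
  ex <- gene$exons[[1]]
  bounds <- c(gene$start, rbind(ex$start, ex$end), gene$end)
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  keep <- ends > starts
  tibble(start = starts[keep], end = ends[keep])
}

#' Build a query index over gene spans
#'
#' Wraps the gene models in a per-chromosome interval index supporting overlap
#' and nearest-gene queries. Queries on a chromosome absent from the index
#' return the empty result. Results are defined to be identical to a linear
#' scan over all genes.
#'
#' @param genes A `gene_models` tibble (non-empty, unique `gene_id`).
#' @return An object of class `feature_index`.
#' @export
build_index <- function(genes) {
  if (nrow(genes) == 0L) abort("cannot index an empty gene set")
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("duplicate gene_id in gene set: '%s'",
                  genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id
  )
  by_chrom <- split(
    tibble(gene_id = genes$gene_id, start = genes$start, end = genes$end,
           strand = genes$strand),
    genes$chrom
  )
  structure(list(genes = genes, gr = gr, by_chrom = by_chrom),
            class = "feature_index")
}

#' Genes overlapping query intervals
#'
#' @param index A `feature_index`.
#' @param chrom,start,end Parallel vectors describing query intervals (0-based
#'   half-open).
#' @return Tibble with columns `query` (index into the query vectors) and
#'   `gene_id`, one row per (query, overlapping gene).
#' @export
index_overlaps <- function(index, chrom, start, end) {
  q <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
  # querying a chromosome absent from the index is legitimate (empty result),
  # so the seqlevel mismatch warning is suppressed
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, index$gr, ignore.strand = TRUE)
  )
  tibble(
    query = S4Vectors::queryHits(hits),
    gene_id = index$gr$gene_id[S4Vectors::subjectHits(hits)]
  ) %>% arrange(.data$query, .data$gene_id)
}

# Genes on one chromosome, or an empty table.
index_chrom <- function(index, chrom) {
  g <- index$by_chrom[[chrom]]
  if (is.null(g)) {
    tibble(gene_id = character(), start = integer(), end = integer(),
           strand = character())
  } else {
    g
  }
}
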