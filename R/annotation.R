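#' Category levels for lncRNA genomic annotation
#'
#' The seven mutually exclusive positional categories of a lncRNA relative to
#' its closest protein-coding gene: within 5' upstream window of the TSS, in
#' the 5'-UTR, in a coding exon, in an intron, in the 3'-UTR, within the 3'
#' downstream window of the TTS, or intergenic.
#'
#' @return Character vector of the seven levels, in display order.
#' @export
annotation_categories <- function() {
  c("upstream", "utr5", "exon", "intron", "utr3", "downstream", "intergenic")
}

#' Closest protein-coding gene per lncRNA
#'
#' Distance is measured from the lncRNA's 5' anchor to the gene span: 0 when
#' the anchor lies inside the span, otherwise the gap in bp. Signs follow the
#' gene's strand frame: negative on the gene's upstream (TSS) side, positive
#' on its downstream (TTS) side. Among genes at equal absolute distance the
#' lexicographically smallest `gene_id` wins; chromosomes with no genes give
#' `NA`.
#'
#' @param lncs A `lnc_loci` tibble.
#' @param index A `feature_index` from [build_index()].
#' @return Tibble with columns `lnc_id`, `closest_gene`, `distance` (signed).
#' @export
closest_pcg <- function(lncs, index) {
  res <- purrr::pmap(
    list(lncs$lnc_id, lncs$chrom, lncs$anchor),
    function(id, chrom, anchor) {
      g <- index_chrom(index, chrom)
      if (nrow(g) == 0L) {
        return(tibble(lnc_id = id, closest_gene = NA_character_,
                      distance = NA_integer_))
      }
      d <- pmax(0L, g$start - anchor, anchor - (g$end - 1L))
      hit <- which(d == min(d))
      hit <- hit[order(g$gene_id[hit])][1]
      tibble(lnc_id = id, closest_gene = g$gene_id[hit],
             distance = signed_gene_distance(anchor, g[hit, ]))
    }
  )
  bind_rows(res)
}

#' Categorize one lncRNA anchor against a gene model
#'
#' Decided by the position of the lncRNA's 5' anchor in the gene's strand
#' frame. Anchors inside the span are `intron` unless exonic; exonic anchors
#' of coding genes are `utr5` when 5' of the CDS, `utr3` when 3' of it, and
#' `exon` within it (or anywhere exonic for non-coding models). Anchors 1 to
#' `upstream_window` bp upstream of the TSS are `upstream`; 1 to
#' `downstream_window` bp downstream of the TTS are `downstream` (both windows
#' inclusive). Everything else — including anchors on chromosomes without any
#' gene — is `intergenic`. The lncRNA's own strand never affects the category.
#'
#' @param anchor 0-based anchor position.
#' @param gene One row of a `gene_models` tibble, or `NULL`.
#' @param upstream_window,downstream_window Window sizes in bp (positive).
#' @return One of [annotation_categories()].
#' @export
categorize_anchor <- function(anchor, gene, upstream_window = 5000,
                              downstream_window = 1000) {
  check_windows(upstream_window, downstream_window)
  if (is.null(gene) || nrow(gene) == 0L) return("intergenic")
  d <- signed_gene_distance(anchor, gene)
  if (d < 0) {
    return(if (-d <= upstream_window) "upstream" else "intergenic")
  }
  if (d > 0) {
    return(if (d <= downstream_window) "downstream" else "intergenic")
  }
  ex <- gene$exons[[1]]
  in_exon <- any(anchor >= ex$start & anchor < ex$end)
  if (!in_exon) return("intron")
  cs <- gene$cds_start[1]
  ce <- gene$cds_end[1]
  if (is.na(cs)) return("exon")
  if (gene$strand[1] == "+") {
    if (anchor < cs) return("utr5")
    if (anchor >= ce) return("utr3")
  } else {
    if (anchor >= ce) return("utr5")
    if (anchor < cs) return("utr3")
  }
  "exon"
}

#' Annotate every lncRNA against its closest protein-coding gene
#'
#' For each locus: find the closest gene ([closest_pcg()]), categorize its
#' anchor ([categorize_anchor()]), and record whether the lncRNA body overlaps
#' the closest gene's span by at least 1 bp (`body_overlaps_gene`). The flag
#' does not change the category — a body-overlapping locus whose anchor falls
#' outside all windows stays `intergenic` — but it feeds the pairing
#' criterion, where any overlap with the closest gene qualifies.
#'
#' @param lncs A `lnc_loci` tibble.
#' @param genes A `gene_models` tibble.
#' @inheritParams categorize_anchor
#' @return Tibble of class `lnc_annotation` with columns `lnc_id`,
#'   `closest_gene`, `distance`, `category` (factor over
#'   [annotation_categories()]) and `body_overlaps_gene`.
#' @export
annotate_lncrnas <- function(lncs, genes, upstream_window = 5000,
                             downstream_window = 1000) {
  check_windows(upstream_window, downstream_window)
  if (nrow(lncs) == 0L) {
    return(structure(
      tibble(lnc_id = character(), closest_gene = character(),
             distance = integer(),
             category = factor(character(), levels = annotation_categories()),
             body_overlaps_gene = logical()),
      class = c("lnc_annotation", class(tibble()))
    ))
  }
  index <- build_index(genes)
  near <- closest_pcg(lncs, index)
  gene_row <- match(near$closest_gene, genes$gene_id)
  category <- purrr::map_chr(seq_len(nrow(lncs)), function(i) {
    gi <- gene_row[i]
    categorize_anchor(
      lncs$anchor[i],
      if (is.na(gi)) NULL else genes[gi, ],
      upstream_window, downstream_window
    )
  })
  overlaps <- !is.na(gene_row) &
    lncs$start < genes$end[gene_row] &
    genes$start[gene_row] < lncs$end
  structure(
    tibble(
      lnc_id = lncs$lnc_id,
      closest_gene = near$closest_gene,
      distance = near$distance,
      category = factor(category, levels = annotation_categories()),
      body_overlaps_gene = overlaps
    ) %>% arrange(.data$lnc_id),
    class = c("lnc_annotation", class(tibble()))
  )
}

#' Category counts and percentages over an annotation subset
#'
#' @param records A `lnc_annotation` tibble.
#' @param subset Optional character vector of `lnc_id`s (must all be present
#'   in `records`); defaults to all records.
#' @return Tibble of class `category_distribution` with one row per category:
#'   `category`, `n`, `percent` (integer-rounded; sums to 100 up to rounding).
#' @export
category_distribution <- function(records, subset = NULL) {
  if (!is.null(subset)) {
    unknown <- setdiff(subset, records$lnc_id)
    if (length(unknown) > 0L) {
      abort(sprintf("unknown lnc_id in subset: '%s'", unknown[1]))
    }
    records <- records %>% filter(.data$lnc_id %in% subset)
  }
  counts <- table(records$category)
  total <- sum(counts)
  out <- tibble(
    category = factor(annotation_categories(), levels = annotation_categories()),
    n = as.integer(counts[annotation_categories()]),
    percent = if (total == 0L) 0L else as.integer(round(100 * as.integer(counts[annotation_categories()]) / total))
  )
  structure(out, class = c("category_distribution", class(tibble())),
            n_total = total)
}

# -- internals ----------------------------------------------------------------

# Signed anchor-to-span distance in the gene's strand frame: 0 inside the
# span, negative upstream of the TSS, positive downstream of the TTS.
signed_gene_distance <- function(anchor, gene) {
  s <- gene$start[1]; e <- gene$end[1]
  if (anchor >= s && anchor < e) return(0L)
  gap <- if (anchor < s) s - anchor else anchor - (e - 1L)
  left <- anchor < s
  upstream_side <- (gene$strand[1] == "+") == left
  as.integer(if (upstream_side) -gap else gap)
}

check_windows <- function(upstream_window, downstream_window) {
  if (upstream_window <= 0 || downstream_window <= 0) {
    abort("annotation windows must be positive")
  }
}
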