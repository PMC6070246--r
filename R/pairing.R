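#' Identify lncRNA-PCG pairs per comparison
#'
#' A lncRNA pairs with its closest protein-coding gene in a comparison when
#' both criteria hold: (1) the lncRNA body overlaps the gene span, or its 5'
#' anchor lies within the upstream/downstream annotation windows of the gene
#' (equivalently, its category is not intergenic); and (2) both the lncRNA and
#' the gene are significantly differentially expressed in that comparison.
#' Pairing is restricted to the closest gene, so each lncRNA yields at most
#' one pair per comparison; a gene may appear in several pairs. Direction
#' concordance is reported but is not a pairing criterion.
#'
#' @param annotations A `lnc_annotation` tibble from [annotate_lncrnas()],
#'   computed against the same gene set as `gene_de`.
#' @param lnc_de,gene_de DE tibbles (shape of [run_de()]) for the lncRNAs and
#'   the protein-coding genes.
#' @param comparisons Character vector of comparison names; default all
#'   comparisons present in `lnc_de`. Each must be present in both DE sets.
#' @return Tibble with columns `lnc_id`, `gene_id`, `comparison`,
#'   `lnc_direction`, `gene_direction`, `concordance` (`"same"`/`"opposite"`),
#'   `category`, `distance`, sorted by comparison then `lnc_id`.
#' @export
identify_pairs <- function(annotations, lnc_de, gene_de, comparisons = NULL) {
  if (is.null(comparisons)) comparisons <- sort(unique(lnc_de$comparison))
  for (cmp in comparisons) {
    if (!cmp %in% lnc_de$comparison) {
      abort(sprintf("comparison '%s' absent from the lncRNA DE results", cmp))
    }
    if (!cmp %in% gene_de$comparison) {
      abort(sprintf("comparison '%s' absent from the PCG DE results", cmp))
    }
  }
  eligible <- annotations %>%
    filter(!is.na(.data$closest_gene),
           .data$body_overlaps_gene | .data$category != "intergenic")
  purrr::map(comparisons, function(cmp) {
    sig_lnc <- lnc_de %>% filter(.data$comparison == cmp, .data$significant)
    sig_gene <- gene_de %>% filter(.data$comparison == cmp, .data$significant)
    eligible %>%
      inner_join(
        sig_lnc %>% select("feature_id", lnc_direction = "direction"),
        by = c(lnc_id = "feature_id")
      ) %>%
      inner_join(
        sig_gene %>% select("feature_id", gene_direction = "direction"),
        by = c(closest_gene = "feature_id")
      ) %>%
      mutate(
        comparison = cmp,
        concordance = ifelse(.data$lnc_direction == .data$gene_direction,
                             "same", "opposite")
      ) %>%
      select("lnc_id", gene_id = "closest_gene", "comparison",
             "lnc_direction", "gene_direction", "concordance",
             "category", "distance")
  }) %>%
    bind_rows() %>%
    arrange(.data$comparison, .data$lnc_id)
}

#' Per-comparison counting chain: DE lncRNAs, annotated, paired
#'
#' Summarises, for each comparison, how many lncRNAs are differentially
#' expressed; how many of those are positionally annotated to their closest
#' gene (non-intergenic category, or a body overlap with the closest gene —
#' i.e. the positional pairing criterion); and how many of those form a
#' lncRNA-PCG pair. The chain is monotone non-increasing by construction:
#' paired lncRNAs are a subset of annotated ones, which are a subset of the
#' differentially expressed ones.
#'
#' @inheritParams identify_pairs
#' @param pairs Optional pre-computed pair table from [identify_pairs()];
#'   recomputed when `NULL`.
#' @return Tibble with columns `comparison`, `n_de_lncrnas`, `n_annotated`,
#'   `n_pairs`.
#' @export
pair_counting_chain <- function(annotations, lnc_de, gene_de,
                                comparisons = NULL, pairs = NULL) {
  if (is.null(comparisons)) comparisons <- sort(unique(lnc_de$comparison))
  if (is.null(pairs)) {
    pairs <- identify_pairs(annotations, lnc_de, gene_de, comparisons)
  }
  eligible_ids <- annotations$lnc_id[
    !is.na(annotations$closest_gene) &
      (annotations$body_overlaps_gene | annotations$category != "intergenic")
  ]
  purrr::map(comparisons, function(cmp) {
    de_ids <- unique(lnc_de$feature_id[lnc_de$comparison == cmp & lnc_de$significant])
    annotated <- intersect(de_ids, eligible_ids)
    paired <- unique(pairs$lnc_id[pairs$comparison == cmp])
    tibble(
      comparison = cmp,
      n_de_lncrnas = length(de_ids),
      n_annotated = length(annotated),
      n_pairs = length(intersect(annotated, paired))
    )
  }) %>% bind_rows()
}
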