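`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force oracles and in-code fixture builders shared across tests.
# Oracles are deliberately naive (double loops, per-base membership) and
# independent of the package's vectorized/indexed implementations.

make_gene <- function(gene_id, chrom, start, end, strand,
                      exons = list(c(start, end)), cds = NULL) {
  structure(
    tibble::tibble(
      gene_id = gene_id, chrom = chrom,
      start = as.integer(start), end = as.integer(end), strand = strand,
      cds_start = if (is.null(cds)) NA_integer_ else as.integer(cds[1]),
      cds_end = if (is.null(cds)) NA_integer_ else as.integer(cds[2]),
      exons = list(tibble::tibble(
        start = as.integer(vapply(exons, `[[`, 0, 1)),
        end = as.integer(vapply(exons, `[[`, 0, 2))
      ))
    ),
    class = c("gene_models", class(tibble::tibble()))
  )
}

bind_genes <- function(...) {
  structure(dplyr::bind_rows(...),
            class = c("gene_models", class(tibble::tibble())))
}

make_lnc <- function(lnc_id, chrom, start, end, strand) {
  structure(
    tibble::tibble(
      lnc_id = lnc_id, chrom = chrom,
      start = as.integer(start), end = as.integer(end), strand = strand,
      anchor = as.integer(if (strand == "+") start else end - 1L)
    ),
    class = c("lnc_loci", class(tibble::tibble()))
  )
}

bind_lncs <- function(...) {
  structure(dplyr::bind_rows(...),
            class = c("lnc_loci", class(tibble::tibble())))
}

# Per-base exon footprint union: every covered base, deduplicated.
oracle_exon_union <- function(starts, ends) {
  bases <- sort(unique(unlist(mapply(function(s, e) seq(s, e - 1L), starts, ends,
                                     SIMPLIFY = FALSE))))
  if (length(bases) == 0L) return(tibble::tibble(start = integer(), end = integer()))
  brk <- c(0L, which(diff(bases) > 1L), length(bases))
  tibble::tibble(
    start = bases[brk[-length(brk)] + 1L],
    end = bases[brk[-1L]] + 1L
  )
}

# Linear scan: closest gene to an anchor with lexicographic tie-break.
# Returns list(gene_id, signed_distance) or NULL if the chromosome is empty.
oracle_closest <- function(chrom, anchor, genes) {
  best <- NULL
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != chrom) next
    d <- if (anchor >= g$start && anchor < g$end) 0L
         else min(abs(anchor - g$start), abs(anchor - (g$end - 1L)))
    if (is.null(best) || d < best$d ||
        (d == best$d && g$gene_id < best$gene_id)) {
      left <- anchor < g$start
      signed <- if (d == 0L) 0L
                else if ((g$strand == "+") == left) -d else d
      best <- list(gene_id = g$gene_id, d = d, signed = signed)
    }
  }
  best
}

# Per-base classifier: explicit position sets for exons, CDS, windows.
oracle_categorize <- function(chrom, anchor, genes,
                              upstream_window = 5000, downstream_window = 1000) {
  best <- oracle_closest(chrom, anchor, genes)
  if (is.null(best)) return("intergenic")
  g <- genes[genes$gene_id == best$gene_id, ]
  ex <- g$exons[[1]]
  exon_bases <- unlist(mapply(function(s, e) seq(s, e - 1L), ex$start, ex$end,
                              SIMPLIFY = FALSE))
  gene_bases <- seq(g$start, g$end - 1L)
  tss <- if (g$strand == "+") g$start else g$end - 1L
  tts <- if (g$strand == "+") g$end - 1L else g$start
  up_bases <- if (g$strand == "+") (tss - upstream_window):(tss - 1L)
              else (tss + 1L):(tss + upstream_window)
  down_bases <- if (g$strand == "+") (tts + 1L):(tts + downstream_window)
                else (tts - downstream_window):(tts - 1L)
  if (anchor %in% gene_bases) {
    if (!(anchor %in% exon_bases)) return("intron")
    if (is.na(g$cds_start)) return("exon")
    cds_bases <- seq(g$cds_start, g$cds_end - 1L)
    five_prime_bases <- if (g$strand == "+") gene_bases[gene_bases < g$cds_start]
                        else gene_bases[gene_bases >= g$cds_end]
    three_prime_bases <- if (g$strand == "+") gene_bases[gene_bases >= g$cds_end]
                         else gene_bases[gene_bases < g$cds_start]
    if (anchor %in% five_prime_bases) return("utr5")
    if (anchor %in% three_prime_bases) return("utr3")
    return("exon")
  }
  if (anchor %in% up_bases) return("upstream")
  if (anchor %in% down_bases) return("downstream")
  "intergenic"
}

# Enumeration oracle for the Venn partition: per-element membership profile.
oracle_venn <- function(sets) {
  nm <- sort(names(sets))
  out <- list()
  for (x in sort(unique(unlist(sets)))) {
    members <- nm[vapply(nm, function(s) x %in% sets[[s]], logical(1))]
    key <- paste(members, collapse = "&")
    out[[key]] <- c(out[[key]], x)
  }
  out
}

# Exhaustive double loop implementing the two pairing criteria verbatim.
oracle_pairs <- function(lncs, genes, annotations_unused, lnc_de, gene_de, comparisons) {
  rows <- list()
  for (cmp in comparisons) {
    for (i in seq_len(nrow(lncs))) {
      l <- lncs[i, ]
      best <- oracle_closest(l$chrom, l$anchor, genes)
      if (is.null(best)) next
      g <- genes[genes$gene_id == best$gene_id, ]
      overlap <- l$start < g$end && g$start < l$end
      cat_l <- oracle_categorize(l$chrom, l$anchor, genes)
      if (!(overlap || cat_l != "intergenic")) next
      sl <- lnc_de[lnc_de$feature_id == l$lnc_id & lnc_de$comparison == cmp, ]
      sg <- gene_de[gene_de$feature_id == g$gene_id & gene_de$comparison == cmp, ]
      if (nrow(sl) == 0L || nrow(sg) == 0L) next
      if (!sl$significant || !sg$significant) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lnc_id = l$lnc_id, gene_id = g$gene_id, comparison = cmp
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(lnc_id = character(), gene_id = character(),
                          comparison = character()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), comparison, lnc_id)
}

# Mirror a genome: coordinates x -> L - x (half-open intervals swap ends),
# strands flip. Categories must be invariant under this reflection.
mirror_genes <- function(genes, L) {
  out <- genes
  out$strand <- ifelse(genes$strand == "+", "-", "+")
  new_start <- L - genes$end
  new_end <- L - genes$start
  out$start <- new_start
  out$end <- new_end
  out$cds_start <- ifelse(is.na(genes$cds_start), NA_integer_, L - genes$cds_end)
  out$cds_end <- ifelse(is.na(genes$cds_end), NA_integer_, L - genes$cds_start)
  out$exons <- lapply(genes$exons, function(ex) {
    tibble::tibble(start = rev(L - ex$end), end = rev(L - ex$start))
  })
  out
}

mirror_lncs <- function(lncs, L) {
  out <- lncs
  out$strand <- ifelse(lncs$strand == "+", "-", "+")
  out$start <- L - lncs$end
  out$end <- L - lncs$start
  out$anchor <- ifelse(out$strand == "+", out$start, out$end - 1L)
  out
}

# Small DE-table builder for set-operation tests.
fake_de <- function(feature_id, comparison, log2fc, significant,
                    p_value = ifelse(significant, 0.01, 0.5)) {
  tibble::tibble(
    feature_id = feature_id, comparison = comparison,
    control_mean = 10, treated_mean = 10 * 2^log2fc,
    log2fc = log2fc, p_value = p_value, adjusted_p = NA_real_,
    significant = significant,
    direction = dplyr::case_when(
      significant & log2fc > 0 ~ "up",
      significant & log2fc < 0 ~ "down",
      .default = "none"
    )
  )
}
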