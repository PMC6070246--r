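#' Read a protein-coding gene annotation from GTF
#'
#' Parses a GTF file into one gene model per gene identifier. Transcript
#' structure is collapsed to the gene level: exons of all transcripts are
#' unioned (overlapping or duplicate exon records merge into one interval) and
#' the coding region is summarised by the outermost bounds over all `CDS`
#' records. Genes without `CDS` records get `NA` coding bounds and are treated
#' as entirely non-coding exonic sequence downstream.
#'
#' GTF coordinates are 1-based inclusive; internally every interval is stored
#' 0-based half-open (`start` inclusive, `end` exclusive), the convention used
#' by every function in this package. The transcription start site (TSS) of a
#' gene is `start` on the `+` strand and `end - 1` on the `-` strand; the
#' transcription termination site (TTS) is the opposite end.
#'
#' @param path Path to a GTF file.
#' @param id_attribute Name of the GTF attribute holding the gene identifier
#'   (default `"gene_id"`).
#' @return A tibble of class `gene_models` with one row per gene and columns
#'   `gene_id`, `chrom`, `start`, `end`, `strand` (`"+"`/`"-"`), `cds_start`,
#'   `cds_end` (0-based half-open, `NA` if non-coding) and `exons`, a
#'   list-column of tibbles with `start`/`end` columns (sorted, disjoint,
#'   contained in the gene span).
#' @export
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'   'chr1\tx\tgene\t101\t500\t.\t+\t.\tgene_id "G1";',
#'   'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "G1";',
#'   'chr1\tx\texon\t401\t500\t.\t+\t.\tgene_id "G1";',
#'   'chr1\tx\tCDS\t151\t450\t.\t+\t.\tgene_id "G1";'
#' ), gtf)
#' read_gene_gtf(gtf)
read_gene_gtf <- function(path, id_attribute = "gene_id") {
  gr <- import_gtf(path)
  ids <- S4Vectors::mcols(gr)[[id_attribute]]
  if (is.null(ids)) {
    abort(sprintf("GTF file '%s' has no '%s' attribute", path, id_attribute))
  }
  df <- tibble(
    id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    rstart = GenomicRanges::start(gr) - 1L,
    rend = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type)
  )
  if (anyNA(df$id)) abort(sprintf("GTF record without '%s' attribute", id_attribute))

  genes <- df %>%
    group_by(.data$id) %>%
    summarise(
      chrom = unique_or_abort(.data$chrom, .data$id[1], "chromosome"),
      strand = unique_or_abort(.data$strand, .data$id[1], "strand"),
      start = if (any(.data$type == "gene")) min(.data$rstart[.data$type == "gene"]) else min(.data$rstart),
      end = if (any(.data$type == "gene")) max(.data$rend[.data$type == "gene"]) else max(.data$rend),
      cds_start = if (any(.data$type == "CDS")) min(.data$rstart[.data$type == "CDS"]) else NA_integer_,
      cds_end = if (any(.data$type == "CDS")) max(.data$rend[.data$type == "CDS"]) else NA_integer_,
      exons = list(union_exons(.data$rstart[.data$type == "exon"], .data$rend[.data$type == "exon"])),
      .groups = "drop"
    ) %>%
    rename(gene_id = "id") %>%
    select("gene_id", "chrom", "start", "end", "strand",
           "cds_start", "cds_end", "exons") %>%
    arrange(.data$gene_id)

  if (any(!genes$strand %in% c("+", "-"))) {
    bad <- genes$gene_id[!genes$strand %in% c("+", "-")][1]
    abort(sprintf("gene '%s' has no usable strand (need '+' or '-')", bad))
  }
  # genes with no exon records are modelled as a single exon over the span
  no_ex <- vapply(genes$exons, nrow, integer(1)) == 0L
  genes$exons[no_ex] <- purrr::map2(
    genes$start[no_ex], genes$end[no_ex],
    function(s, e) tibble(start = s, end = e)
  )
  purrr::pwalk(
    list(genes$gene_id, genes$start, genes$end, genes$exons, genes$cds_start, genes$cds_end),
    function(id, s, e, ex, cs, ce) {
      if (any(ex$start < s) || any(ex$end > e)) {
        abort(sprintf("gene '%s': exon outside declared gene span", id))
      }
      if (!is.na(cs) && (cs < s || ce > e)) {
        abort(sprintf("gene '%s': CDS outside declared gene span", id))
      }
    }
  )
  structure(genes, class = c("gene_models", class(tibble())))
}

#' Read a lncRNA annotation from GTF
#'
#' Each lncRNA gene identifier becomes one locus spanning all of its records.
#' The locus `anchor` is the genomic position of its 5' end: `start` on the
#' `+` strand, `end - 1` on the `-` strand (0-based). Categorization of a
#' lncRNA relative to its closest protein-coding gene keys on this anchor.
#'
#' @inheritParams read_gene_gtf
#' @return A tibble of class `lnc_loci` with columns `lnc_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand` and `anchor`.
#' @export
read_lncrna_gtf <- function(path, id_attribute = "gene_id") {
  gr <- import_gtf(path)
  ids <- S4Vectors::mcols(gr)[[id_attribute]]
  if (is.null(ids)) {
    abort(sprintf("GTF file '%s' has no '%s' attribute", path, id_attribute))
  }
  loci <- tibble(
    id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    rstart = GenomicRanges::start(gr) - 1L,
    rend = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) %>%
    group_by(.data$id) %>%
    summarise(
      chrom = unique_or_abort(.data$chrom, .data$id[1], "chromosome"),
      strand = unique_or_abort(.data$strand, .data$id[1], "strand"),
      start = min(.data$rstart),
      end = max(.data$rend),
      .groups = "drop"
    ) %>%
    rename(lnc_id = "id") %>%
    select("lnc_id", "chrom", "start", "end", "strand") %>%
    arrange(.data$lnc_id)
  if (any(!loci$strand %in% c("+", "-"))) {
    bad <- loci$lnc_id[!loci$strand %in% c("+", "-")][1]
    abort(sprintf("lncRNA '%s' has no usable strand (need '+' or '-')", bad))
  }
  loci$anchor <- ifelse(loci$strand == "+", loci$start, loci$end - 1L)
  structure(loci, class = c("lnc_loci", class(tibble())))
}

#' Write gene models back to GTF
#'
#' Emits the same dialect `read_gene_gtf()` consumes: one `gene` record per
#' gene, one `exon` record per (unioned) exon and, for coding genes, `CDS`
#' records covering the intersection of the coding bounds with the exons.
#' Re-reading the file reproduces the models exactly.
#'
#' @param genes A `gene_models` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gtf <- function(genes, path) {
  rows <- purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$start, genes$end, genes$strand,
         genes$cds_start, genes$cds_end, genes$exons),
    function(id, chrom, s, e, strand, cs, ce, ex) {
      out <- tibble(
        chrom = chrom, start = c(s, ex$start), end = c(e, ex$end),
        strand = strand, type = c("gene", rep("exon", nrow(ex))), gene_id = id
      )
      if (!is.na(cs)) {
        cds <- tibble(start = pmax(ex$start, cs), end = pmin(ex$end, ce)) %>%
          filter(.data$start < .data$end)
        if (nrow(cds) == 0L) cds <- tibble(start = cs, end = ce)
        out <- bind_rows(out, tibble(
          chrom = chrom, start = cds$start, end = cds$end,
          strand = strand, type = "CDS", gene_id = id
        ))
      }
      out
    }
  ) %>% bind_rows()
  export_gtf(rows, path)
}

#' Write lncRNA loci to GTF
#'
#' @param lncs A `lnc_loci` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lncrna_gtf <- function(lncs, path) {
  export_gtf(
    tibble(
      chrom = lncs$chrom, start = lncs$start, end = lncs$end,
      strand = lncs$strand, type = "gene", gene_id = lncs$lnc_id
    ),
    path
  )
}

# -- internals ----------------------------------------------------------------

# Pre-scan a GTF file so malformed input fails with a line number, then
# delegate parsing to rtracklayer.
import_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  lineno <- which(body)
  n_fields <- lengths(fields)
  if (any(n_fields != 9L)) {
    i <- which(n_fields != 9L)[1]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                  lineno[i], n_fields[i]))
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  bad <- is.na(starts) | is.na(ends) | starts < 1 | ends < starts
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("malformed GTF line %d: invalid coordinates '%s'-'%s'",
                  lineno[i], fields[[i]][4], fields[[i]][5]))
  }
  rtracklayer::import(path, format = "gtf")
}

# rows: tibble with chrom, start, end (0-based half-open), strand, type, gene_id
export_gtf <- function(rows, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = rows$strand,
    type = rows$type,
    source = "lncpair",
    phase = ifelse(rows$type == "CDS", 0L, NA_integer_),
    gene_id = rows$gene_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

union_exons <- function(starts, ends) {
  if (length(starts) == 0L) return(tibble(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

unique_or_abort <- function(x, id, what) {
  u <- unique(x)
  if (length(u) != 1L) {
    abort(sprintf("gene '%s' has records on more than one %s", id, what))
  }
  u
}
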