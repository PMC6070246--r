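#' Pipeline configuration
#'
#' One object drives a full run; every threshold defaults to the study's
#' values (presence cutoff 1 FPKM, alpha 0.05, windows 5000/1000 bp).
#'
#' @param gene_gtf,lncrna_gtf Paths to the PCG and lncRNA GTF annotations.
#' @param expression Path to the FPKM TSV (`feature_id` + one column per
#'   sample; PCGs and lncRNAs may share one table).
#' @param groups Path to the two-column sample-to-group TSV (`sample_id`,
#'   `group`).
#' @param de_table Optional path to an externally computed DE TSV (see
#'   [import_de_table()]); when given, the built-in test is skipped.
#' @param comparisons Contrast tibble (`name`, `control`, `treated`).
#' @param alpha,adjust Significance level and p-value adjustment for
#'   [run_de()].
#' @param expression_cutoff Presence cutoff in mean FPKM.
#' @param upstream_window,downstream_window Annotation windows (bp).
#' @param top_k Rows per top-regulated table.
#' @param seed Integer seed recorded with the run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_gtf, lncrna_gtf, expression, groups,
                            de_table = NULL,
                            comparisons = default_comparisons(),
                            alpha = 0.05, adjust = "none",
                            expression_cutoff = 1,
                            upstream_window = 5000, downstream_window = 1000,
                            top_k = 10, seed = 1L) {
  cfg <- as.list(environment())
  if (any(comparisons$control == comparisons$treated)) {
    abort("a comparison must contrast two distinct groups")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' One `key = value` pair per line (`#` comments allowed). Keys are the
#' arguments of [pipeline_config()]; `comparisons` is a semicolon-separated
#' list of `name:control:treated` triples.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) abort(sprintf("config line without '=': '%s'", lines[bad][1]))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  args <- as.list(setNames(vals, keys))
  for (num in c("alpha", "expression_cutoff", "upstream_window",
                "downstream_window", "top_k", "seed")) {
    if (num %in% names(args)) args[[num]] <- as.numeric(args[[num]])
  }
  if ("comparisons" %in% names(args)) {
    triples <- strsplit(strsplit(args$comparisons, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    if (any(lengths(triples) != 3L)) {
      abort("each comparison must be 'name:control:treated'")
    }
    args$comparisons <- tibble(
      name = vapply(triples, `[[`, "", 1L),
      control = vapply(triples, `[[`, "", 2L),
      treated = vapply(triples, `[[`, "", 3L)
    )
  }
  do.call(pipeline_config, args)
}

#' Run the full lncRNA-PCG co-regulation pipeline
#'
#' Executes, in order: annotation and expression loading; presence filtering;
#' per-comparison differential expression (built-in Welch test, or an
#' imported external table); the not-expressed/stable/differential partition
#' for PCGs and lncRNAs; top-regulated PCG tables; genomic annotation of the
#' lncRNAs against their closest PCG; category distributions of the DE
#' lncRNAs per comparison; four-set Venn partitions; directional pattern
#' classification; lncRNA-PCG pair identification; and the per-comparison
#' counting chain. Stage-wise feature counts are logged via [message()]; any
#' stage error aborts naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return List of class `lnc_report` with elements `genes`, `lncs`,
#'   `partition` (`$pcg`, `$lnc`), `de` (`$pcg`, `$lnc`), `top` (per
#'   comparison: `$increase`, `$decrease`), `annotation`,
#'   `category_distributions` (per comparison), `venn` (`$pcg`, `$lnc`),
#'   `patterns` (`$pcg`, `$lnc`), `pairs`, `chain` and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  genes <- stage("load gene GTF", read_gene_gtf(config$gene_gtf))
  lncs <- stage("load lncRNA GTF", read_lncrna_gtf(config$lncrna_gtf))
  expr <- stage("load expression",
                readr::read_tsv(config$expression, show_col_types = FALSE))
  groups <- stage("load groups",
                  readr::read_tsv(config$groups, show_col_types = FALSE))
  message(sprintf("loaded %d PCGs, %d lncRNAs, %d features x %d samples (seed %d)",
                  nrow(genes), nrow(lncs), nrow(expr), ncol(expr) - 1L,
                  as.integer(config$seed)))

  known <- c(genes$gene_id, lncs$lnc_id)
  stray <- setdiff(expr$feature_id, known)
  if (length(stray) > 0L) {
    message(sprintf("dropping %d expression features absent from both annotations", length(stray)))
    expr <- expr %>% filter(.data$feature_id %in% known)
  }
  expr_pcg <- expr %>% filter(.data$feature_id %in% genes$gene_id)
  expr_lnc <- expr %>% filter(.data$feature_id %in% lncs$lnc_id)

  expressed_pcg <- stage("presence filter (PCG)",
                         expressed_features(expr_pcg, groups, config$expression_cutoff))
  expressed_lnc <- stage("presence filter (lncRNA)",
                         expressed_features(expr_lnc, groups, config$expression_cutoff))
  message(sprintf("expressed: %d/%d PCGs, %d/%d lncRNAs",
                  length(expressed_pcg), nrow(expr_pcg),
                  length(expressed_lnc), nrow(expr_lnc)))

  if (is.null(config$de_table)) {
    de_pcg <- stage("differential expression (PCG)",
                    run_de(expr_pcg, groups, config$comparisons,
                           alpha = config$alpha, adjust = config$adjust,
                           features = expressed_pcg))
    de_lnc <- stage("differential expression (lncRNA)",
                    run_de(expr_lnc, groups, config$comparisons,
                           alpha = config$alpha, adjust = config$adjust,
                           features = expressed_lnc))
  } else {
    de_all <- stage("import DE table",
                    import_de_table(config$de_table, alpha = config$alpha,
                                    adjust = config$adjust))
    de_pcg <- de_all %>% filter(.data$feature_id %in% genes$gene_id)
    de_lnc <- de_all %>% filter(.data$feature_id %in% lncs$lnc_id)
  }
  message(sprintf("significant calls: %d PCG, %d lncRNA",
                  sum(de_pcg$significant), sum(de_lnc$significant)))

  part_pcg <- stage("partition (PCG)",
                    partition_features(expr_pcg, groups, de_pcg, config$expression_cutoff))
  part_lnc <- stage("partition (lncRNA)",
                    partition_features(expr_lnc, groups, de_lnc, config$expression_cutoff))

  cmp_names <- config$comparisons$name
  top <- stage("top-regulated tables", purrr::map(
    setNames(cmp_names, cmp_names),
    function(cmp) top_regulated(de_pcg %>% filter(.data$comparison == cmp),
                                k = config$top_k)
  ))

  annotation <- stage("genomic annotation",
                      annotate_lncrnas(lncs, genes, config$upstream_window,
                                       config$downstream_window))
  de_lnc_ids <- purrr::map(
    setNames(cmp_names, cmp_names),
    function(cmp) unique(de_lnc$feature_id[de_lnc$comparison == cmp & de_lnc$significant])
  )
  dists <- stage("category distributions", purrr::map(
    de_lnc_ids, function(ids) category_distribution(annotation, subset = ids)
  ))

  sets_pcg <- purrr::map(
    setNames(cmp_names, cmp_names),
    function(cmp) unique(de_pcg$feature_id[de_pcg$comparison == cmp & de_pcg$significant])
  )
  venn <- stage("venn partitions",
                list(pcg = venn_partition(sets_pcg), lnc = venn_partition(de_lnc_ids)))
  patterns <- stage("pattern classification",
                    list(pcg = classify_patterns(de_pcg, cmp_names),
                         lnc = classify_patterns(de_lnc, cmp_names)))
  pairs <- stage("pair identification",
                 identify_pairs(annotation, de_lnc, de_pcg, cmp_names))
  chain <- stage("counting chain",
                 pair_counting_chain(annotation, de_lnc, de_pcg, cmp_names,
                                     pairs = pairs))
  message(sprintf("pairs: %d across %d comparisons", nrow(pairs), length(cmp_names)))

  structure(
    list(genes = genes, lncs = lncs,
         partition = list(pcg = part_pcg, lnc = part_lnc),
         de = list(pcg = de_pcg, lnc = de_lnc),
         top = top, annotation = annotation,
         category_distributions = dists,
         venn = venn, patterns = patterns,
         pairs = pairs, chain = chain, config = config),
    class = "lnc_report"
  )
}

#' Top-regulated feature tables for one comparison
#'
#' Significant features ranked by fold change in the dual presentation: one
#' table of inductions by descending fold-increase and one of repressions by
#' descending percent decrease. Ties break by feature id.
#'
#' @param de DE tibble restricted to a single comparison.
#' @param k Maximum rows per table (>= 1). Fewer significant features give a
#'   shorter table.
#' @param eps Fold-change pseudocount.
#' @return List with tibbles `increase` (`feature_id`, means, `ratio`,
#'   `fold_change` formatted) and `decrease` (`feature_id`, means, `ratio`,
#'   `pct_decrease` formatted).
#' @export
top_regulated <- function(de, k = 10, eps = 0.001) {
  if (k < 1) abort("k must be at least 1")
  if (length(unique(de$comparison)) > 1L) {
    abort("top_regulated expects DE results for a single comparison")
  }
  sig <- de %>%
    filter(.data$significant) %>%
    mutate(ratio = fold_change_ratio(.data$control_mean, .data$treated_mean, eps))
  up <- sig %>%
    filter(.data$ratio >= 1) %>%
    arrange(dplyr::desc(.data$ratio), .data$feature_id) %>%
    head(k) %>%
    mutate(fold_change = format_fold_change(.data$control_mean, .data$treated_mean, eps)) %>%
    select("feature_id", "control_mean", "treated_mean", "ratio", "fold_change")
  dn <- sig %>%
    filter(.data$ratio < 1) %>%
    arrange(.data$ratio, .data$feature_id) %>%
    head(k) %>%
    mutate(pct_decrease = format_fold_change(.data$control_mean, .data$treated_mean, eps)) %>%
    select("feature_id", "control_mean", "treated_mean", "ratio", "pct_decrease")
  list(increase = up, decrease = dn)
}

#' Write a report bundle to TSV files
#'
#' Emits every table of an `lnc_report` as a TSV under `dir`. Identical
#' bundles produce byte-identical files.
#'
#' @param report An `lnc_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(dir, name))
  w(tidy(report$partition$pcg), "partition_pcg.tsv")
  w(tidy(report$partition$lnc), "partition_lnc.tsv")
  w(report$de$pcg, "de_pcg.tsv")
  w(report$de$lnc, "de_lnc.tsv")
  w(as_tibble(report$annotation), "annotation.tsv")
  for (cmp in names(report$category_distributions)) {
    w(as_tibble(report$category_distributions[[cmp]]),
      sprintf("category_distribution_%s.tsv", cmp))
  }
  for (cmp in names(report$top)) {
    w(report$top[[cmp]]$increase, sprintf("top_increase_%s.tsv", cmp))
    w(report$top[[cmp]]$decrease, sprintf("top_decrease_%s.tsv", cmp))
  }
  w(tidy(report$venn$pcg), "venn_pcg.tsv")
  w(tidy(report$venn$lnc), "venn_lnc.tsv")
  w(report$patterns$pcg, "patterns_pcg.tsv")
  w(report$patterns$lnc, "patterns_lnc.tsv")
  w(report$pairs, "pairs.tsv")
  w(report$chain, "counting_chain.tsv")
  invisible(dir)
}
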