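#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the simulated study: genome layout, lncRNA category
#' mix, group structure, expression baselines, planted effects and planted
#' lncRNA-PCG pairs. Defaults emulate the multi-group liver RNA-seq design the
#' pipeline targets: six groups with unbalanced sizes (3, 4, 2, 3, 3, 3)
#' including an n = 2 group, four treated-vs-vehicle comparisons, a large
#' non-expressed fraction, log-normal baselines, and lncRNA categories at the
#' proportions observed for differentially regulated liver lncRNAs
#' (intron 44%, intergenic 26%, 3'-UTR 16%, downstream 5%, upstream 4%,
#' exon 4%, 5'-UTR 1%).
#'
#' @param n_genes,n_lncrnas Feature counts.
#' @param n_chromosomes Chromosomes genes are distributed over (round-robin).
#' @param exon_count Integer range of exons per gene (min must be >= 2 so
#'   every gene has an intron).
#' @param exon_length,intron_length,utr_length,gene_gap,lnc_length Integer
#'   ranges (bp) for gene structure, inter-gene gaps and lncRNA lengths.
#' @param category_proportions Named numeric over the seven
#'   [annotation_categories()], summing to 1; converted to exact quota counts.
#' @param groups,group_sizes Group labels and per-group sample counts.
#' @param comparisons Tibble of contrasts (`name`, `control`, `treated`);
#'   treated groups must be distinct across comparisons.
#' @param fraction_nonexpressed Fraction of features given sub-threshold
#'   baselines.
#' @param baseline_meanlog,baseline_sdlog Log-normal (natural-log scale)
#'   baseline FPKM parameters for expressed features.
#' @param nonexpressed_max Upper bound of the uniform baseline for
#'   non-expressed features (FPKM).
#' @param de_fraction Fraction of eligible expressed features given a planted
#'   effect, per comparison.
#' @param effect_size Magnitude of planted effects (|log2 fold-change|).
#' @param noise_sd Multiplicative noise sd on the log2 scale.
#' @param n_pairs Number of deliberately planted co-regulated lncRNA-PCG
#'   pairs (lncRNA placed in an intron of its partner gene).
#' @param pair_concordance_same Probability a planted pair is co-regulated in
#'   the same direction (vs opposite).
#' @param upstream_window,downstream_window Annotation windows (bp).
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60,
                       n_lncrnas = 150,
                       n_chromosomes = 4,
                       exon_count = c(2L, 5L),
                       exon_length = c(120L, 400L),
                       intron_length = c(500L, 3000L),
                       utr_length = c(30L, 80L),
                       gene_gap = c(30000L, 50000L),
                       lnc_length = c(200L, 2000L),
                       category_proportions = c(
                         upstream = 0.04, utr5 = 0.01, exon = 0.04,
                         intron = 0.44, utr3 = 0.16, downstream = 0.05,
                         intergenic = 0.26
                       ),
                       groups = c("CV_CO", "CV_BDE-47", "CV_BDE-99",
                                  "GF_CO", "GF_BDE-47", "GF_BDE-99"),
                       group_sizes = c(3L, 4L, 2L, 3L, 3L, 3L),
                       comparisons = default_comparisons(),
                       fraction_nonexpressed = 0.5,
                       baseline_meanlog = 2,
                       baseline_sdlog = 1,
                       nonexpressed_max = 0.1,
                       de_fraction = 0.10,
                       effect_size = 2,
                       noise_sd = 0.25,
                       n_pairs = 25,
                       pair_concordance_same = 0.8,
                       upstream_window = 5000,
                       downstream_window = 1000,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (length(groups) != length(group_sizes)) {
    abort("groups and group_sizes must have the same length")
  }
  if (any(group_sizes < 1L)) abort("every group needs at least one sample")
  if (n_genes < 1L || n_lncrnas < 0L) abort("feature counts must be positive")
  if (exon_count[1] < 2L) abort("exon_count minimum must be >= 2 (genes need an intron)")
  if (!setequal(names(category_proportions), annotation_categories())) {
    abort("category_proportions must name exactly the seven annotation categories")
  }
  if (abs(sum(category_proportions) - 1) > 1e-8) {
    abort("category_proportions must sum to 1")
  }
  bad_group <- setdiff(c(comparisons$control, comparisons$treated), groups)
  if (length(bad_group) > 0L) {
    abort(sprintf("comparison group '%s' is not a simulated group", bad_group[1]))
  }
  if (anyDuplicated(comparisons$treated)) {
    abort("treated groups must be distinct across comparisons")
  }
  if (any(comparisons$control == comparisons$treated)) {
    abort("a comparison must contrast two distinct groups")
  }
  quota <- quota_counts(n_lncrnas, category_proportions[annotation_categories()])
  if (n_pairs > quota[["intron"]]) {
    abort(sprintf("infeasible config: %d planted pairs need intron loci but the intron quota is %d",
                  n_pairs, quota[["intron"]]))
  }
  if (n_pairs > n_genes) abort("cannot plant more pairs than genes")
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with lncRNAs planted at known categories
#'
#' Lays out non-overlapping protein-coding gene models (exons, introns, UTRs,
#' CDS) along the chromosomes with wide inter-gene gaps, then places each
#' lncRNA so that its 5' anchor realizes a planted category against a target
#' gene. Category counts follow the configured proportions exactly (largest-
#' remainder quota). The first `n_pairs` intronic lncRNAs are reserved as
#' planted co-regulated pairs with their host gene. The planted annotation is
#' verified internally by re-annotating the emitted loci; any disagreement is
#' an error.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (`gene_models`), `lncs` (`lnc_loci`) and `truth`
#'   (list: `lnc` category/target table, `pairs` table with planted comparison
#'   and concordance, `annotation` as recomputed by [annotate_lncrnas()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- layout_genes(config)
  quota <- quota_counts(config$n_lncrnas,
                        config$category_proportions[annotation_categories()])
  categories <- sample(rep(annotation_categories(), quota))
  lnc_ids <- sprintf("LNC%05d", seq_len(config$n_lncrnas))

  # planted pairs: intronic lncRNAs hosted by distinct genes
  pair_lnc <- head(which(categories == "intron"), config$n_pairs)
  target <- sample(genes$gene_id, config$n_lncrnas, replace = TRUE)
  if (config$n_pairs > 0L) {
    target[pair_lnc] <- sample(genes$gene_id, config$n_pairs)
  }

  empty_loci <- tibble(lnc_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), anchor = integer())
  lncs <- purrr::map(seq_len(config$n_lncrnas), function(i) {
    g <- genes[genes$gene_id == target[i], ]
    anchor <- place_anchor(categories[i], g, config)
    len <- sample(config$lnc_length[1]:config$lnc_length[2], 1L)
    strand <- sample(c("+", "-"), 1L)
    tibble(
      lnc_id = lnc_ids[i],
      chrom = g$chrom,
      start = if (strand == "+") anchor else anchor - len + 1L,
      end = if (strand == "+") anchor + len else anchor + 1L,
      strand = strand,
      anchor = anchor
    )
  }) %>% bind_rows(empty_loci)
  lncs <- structure(arrange(lncs, .data$lnc_id),
                    class = c("lnc_loci", class(tibble())))

  pairs <- tibble(
    lnc_id = lnc_ids[pair_lnc],
    gene_id = target[pair_lnc],
    comparison = sample(config$comparisons$name, config$n_pairs, replace = TRUE),
    concordance = ifelse(
      runif(config$n_pairs) < config$pair_concordance_same, "same", "opposite"
    )
  )

  truth_lnc <- tibble(lnc_id = lnc_ids, category = categories,
                      target_gene = target) %>% arrange(.data$lnc_id)

  annotation <- if (config$n_lncrnas > 0L) {
    annotate_lncrnas(lncs, genes, config$upstream_window, config$downstream_window)
  } else {
    annotate_lncrnas(lncs[0, ], genes)
  }
  mism <- as.character(annotation$category[match(truth_lnc$lnc_id, annotation$lnc_id)]) !=
    truth_lnc$category
  if (any(mism)) {
    abort(sprintf("internal placement error: lncRNA '%s' planted as '%s' but re-annotated as '%s'",
                  truth_lnc$lnc_id[mism][1], truth_lnc$category[mism][1],
                  as.character(annotation$category[match(truth_lnc$lnc_id, annotation$lnc_id)])[mism][1]))
  }
  list(genes = genes, lncs = lncs,
       truth = list(lnc = truth_lnc, pairs = pairs, annotation = annotation))
}

#' Simulate a multi-group FPKM matrix with planted effects
#'
#' FPKM for feature f in a sample of group g is
#' `baseline_f * 2^(effect_{f,g} + N(0, noise_sd))`. Expressed features draw
#' log-normal baselines; a configured fraction draws sub-threshold baselines
#' instead (below the presence cutoff in expectation). Planted pairs from the
#' genome step receive effects of magnitude `effect_size` in their planted
#' comparison's treated group, with the pair's two members sharing or opposing
#' sign per the planted concordance; additionally a fraction of the remaining
#' expressed features receives independent planted effects per comparison.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()], or `NULL` for a genome-free
#'   matrix (generic feature ids, no planted pairs) — useful for pure
#'   expression calibration runs.
#' @return List with `expr` (tibble, `feature_id` + sample columns), `groups`
#'   (sample/group map), and `truth` (list: `expressed` ids, `effects` tibble
#'   of planted log2 fold-changes, `expected_pairs` — every lncRNA-closest-
#'   gene pair satisfying the positional criterion whose members both carry
#'   planted effects in the same comparison).
#' @export
simulate_expression <- function(config, genome = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ids <- if (is.null(genome)) {
    sprintf("F%05d", seq_len(config$n_genes + config$n_lncrnas))
  } else {
    c(genome$genes$gene_id, genome$lncs$lnc_id)
  }
  n <- length(ids)
  pair_members <- if (is.null(genome)) character() else
    unique(c(genome$truth$pairs$lnc_id, genome$truth$pairs$gene_id))

  n_expr <- max(round((1 - config$fraction_nonexpressed) * n), length(pair_members))
  expressed <- union(pair_members,
                     sample(setdiff(ids, pair_members),
                            max(0L, n_expr - length(pair_members))))
  baseline <- setNames(runif(n, 1e-3, config$nonexpressed_max), ids)
  baseline[expressed] <- stats::rlnorm(length(expressed),
                                       config$baseline_meanlog,
                                       config$baseline_sdlog)

  cmp <- config$comparisons
  effects <- matrix(0, nrow = n, ncol = nrow(cmp),
                    dimnames = list(ids, cmp$name))
  if (!is.null(genome) && nrow(genome$truth$pairs) > 0L) {
    p <- genome$truth$pairs
    lnc_sign <- sample(c(1, -1), nrow(p), replace = TRUE)
    gene_sign <- ifelse(p$concordance == "same", lnc_sign, -lnc_sign)
    for (i in seq_len(nrow(p))) {
      effects[p$lnc_id[i], p$comparison[i]] <- lnc_sign[i] * config$effect_size
      effects[p$gene_id[i], p$comparison[i]] <- gene_sign[i] * config$effect_size
    }
  }
  candidates <- setdiff(expressed, pair_members)
  for (j in seq_len(nrow(cmp))) {
    k <- floor(config$de_fraction * length(candidates))
    if (k > 0L) {
      chosen <- sample(candidates, k)
      effects[chosen, j] <- sample(c(1, -1), k, replace = TRUE) * config$effect_size
    }
  }

  samples <- tibble(
    sample_id = unlist(purrr::map2(config$groups, config$group_sizes,
                                   function(g, k) sprintf("%s_s%d", g, seq_len(k)))),
    group = rep(config$groups, config$group_sizes)
  )
  treated_of <- setNames(rep(NA_character_, length(config$groups)), config$groups)
  treated_of[cmp$treated] <- cmp$name
  m <- matrix(0, nrow = n, ncol = nrow(samples),
              dimnames = list(ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    cmp_name <- treated_of[[samples$group[j]]]
    eff <- if (is.na(cmp_name)) 0 else effects[, cmp_name]
    m[, j] <- baseline * 2^(eff + rnorm(n, 0, config$noise_sd))
  }

  effects_long <- as_tibble(as.table(effects), .name_repair = "minimal") %>%
    setNames(c("feature_id", "comparison", "log2fc")) %>%
    mutate(feature_id = as.character(.data$feature_id),
           comparison = as.character(.data$comparison)) %>%
    filter(.data$log2fc != 0) %>%
    arrange(.data$comparison, .data$feature_id)

  expected_pairs <- expected_pairs_from_effects(genome, effects_long)

  list(
    expr = bind_cols(tibble(feature_id = ids), as_tibble(m, .name_repair = "minimal")),
    groups = samples,
    truth = list(expressed = sort(expressed), effects = effects_long,
                 expected_pairs = expected_pairs)
  )
}

#' Simulate a complete study bundle
#'
#' Runs [simulate_genome()] and [simulate_expression()] and merges the ground
#' truth. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study`: `genes`, `lncs`, `expr`, `groups`,
#'   `truth` (lnc categories/targets, planted pairs, annotation, expressed
#'   set, planted effects, expected pairs) and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  ex <- simulate_expression(config, genome)
  structure(
    list(genes = genome$genes, lncs = genome$lncs, expr = ex$expr,
         groups = ex$groups,
         truth = c(genome$truth, ex$truth),
         config = config),
    class = "sim_study"
  )
}

#' Write a simulated study to plain-text fixture files
#'
#' Emits `genes.gtf`, `lncrnas.gtf`, `expression.tsv`, `groups.tsv` and
#' `truth.tsv` (one row per feature: type, planted category/target for
#' lncRNAs, pair membership, expression status, and one planted-effect column
#' per comparison). Re-reading with [read_fixture()] reproduces the tables.
#'
#' @param study A `sim_study` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gene_gtf(study$genes, file.path(dir, "genes.gtf"))
  write_lncrna_gtf(study$lncs, file.path(dir, "lncrnas.gtf"))
  readr::write_tsv(study$expr, file.path(dir, "expression.tsv"))
  readr::write_tsv(study$groups, file.path(dir, "groups.tsv"))
  readr::write_tsv(truth_table(study), file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a fixture directory back
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `genes`, `lncs`, `expr`, `groups` and `truth` (the flat
#'   per-feature truth table).
#' @export
read_fixture <- function(dir) {
  list(
    genes = read_gene_gtf(file.path(dir, "genes.gtf")),
    lncs = read_lncrna_gtf(file.path(dir, "lncrnas.gtf")),
    expr = readr::read_tsv(file.path(dir, "expression.tsv"), show_col_types = FALSE),
    groups = readr::read_tsv(file.path(dir, "groups.tsv"), show_col_types = FALSE),
    truth = readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  )
}

#' Flat per-feature ground-truth table of a simulated study
#'
#' @param study A `sim_study` bundle.
#' @return Tibble with one row per feature (`n_genes + n_lncrnas` rows).
#' @export
truth_table <- function(study) {
  ids <- c(study$genes$gene_id, study$lncs$lnc_id)
  out <- tibble(
    feature_id = ids,
    type = rep(c("pcg", "lnc"), c(nrow(study$genes), nrow(study$lncs)))
  ) %>%
    left_join(study$truth$lnc, by = c(feature_id = "lnc_id")) %>%
    mutate(
      expressed = .data$feature_id %in% study$truth$expressed,
      is_pair = .data$feature_id %in% c(study$truth$pairs$lnc_id,
                                        study$truth$pairs$gene_id)
    )
  eff <- study$truth$effects %>%
    tidyr::pivot_wider(names_from = "comparison", values_from = "log2fc",
                       names_prefix = "effect_", values_fill = 0)
  out %>% left_join(eff, by = "feature_id") %>%
    mutate(across(dplyr::starts_with("effect_"), ~ tidyr::replace_na(.x, 0)))
}

# -- internals ----------------------------------------------------------------

# Largest-remainder apportionment of n into quota counts at the given
# proportions; exact (sums to n).
quota_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0L) {
    topup <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[topup] <- counts[topup] + 1L
  }
  setNames(as.integer(counts), names(proportions))
}

layout_genes <- function(config) {
  cursor <- rep(0L, config$n_chromosomes)
  rows <- purrr::map(seq_len(config$n_genes), function(i) {
    ch <- ((i - 1L) %% config$n_chromosomes) + 1L
    n_ex <- sample(config$exon_count[1]:config$exon_count[2], 1L)
    ex_len <- sample(config$exon_length[1]:config$exon_length[2], n_ex, replace = TRUE)
    in_len <- sample(config$intron_length[1]:config$intron_length[2], n_ex - 1L,
                     replace = TRUE)
    gap <- sample(config$gene_gap[1]:config$gene_gap[2], 1L)
    start <- cursor[ch] + gap
    ex_start <- start + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len
    end <- ex_end[n_ex]
    strand <- sample(c("+", "-"), 1L)
    # UTR lengths carved out of the terminal exons; 5' UTR sits at the
    # genomic left end on '+', at the right end on '-'
    u5 <- sample(config$utr_length[1]:config$utr_length[2], 1L)
    u3 <- sample(config$utr_length[1]:config$utr_length[2], 1L)
    left <- if (strand == "+") u5 else u3
    right <- if (strand == "+") u3 else u5
    cursor[ch] <<- end
    tibble(
      gene_id = sprintf("PCG%05d", i),
      chrom = sprintf("chr%d", ch),
      start = start, end = end, strand = strand,
      cds_start = start + left, cds_end = end - right,
      exons = list(tibble(start = ex_start, end = ex_end))
    )
  })
  structure(bind_rows(rows) %>% arrange(.data$gene_id),
            class = c("gene_models", class(tibble())))
}

# Anchor position realizing `category` against gene g (one row).
place_anchor <- function(category, g, config) {
  up <- config$upstream_window
  down <- config$downstream_window
  tss <- gene_tss(g)
  tts <- gene_tts(g)
  plus <- g$strand == "+"
  switch(category,
    upstream = if (plus) tss - sample.int(up, 1L) else tss + sample.int(up, 1L),
    downstream = if (plus) tts + sample.int(down, 1L) else tts - sample.int(down, 1L),
    intron = sample_interval(gene_introns(g)),
    exon = sample_interval(clip_intervals(g$exons[[1]], g$cds_start, g$cds_end)),
    utr5 = sample_interval(if (plus) clip_intervals(g$exons[[1]], g$start, g$cds_start)
                           else clip_intervals(g$exons[[1]], g$cds_end, g$end)),
    utr3 = sample_interval(if (plus) clip_intervals(g$exons[[1]], g$cds_end, g$end)
                           else clip_intervals(g$exons[[1]], g$start, g$cds_start)),
    intergenic = g$end - 1L + 10000L + sample.int(4001L, 1L) - 1L,
    abort(sprintf("unknown category '%s'", category))
  )
}

clip_intervals <- function(iv, lo, hi) {
  out <- tibble(start = pmax(iv$start, lo), end = pmin(iv$end, hi))
  out[out$start < out$end, , drop = FALSE]
}

# Uniformly sample one position from a set of disjoint intervals.
sample_interval <- function(iv) {
  if (nrow(iv) == 0L) abort("infeasible config: no genomic space for a planted category")
  w <- iv$end - iv$start
  i <- sample.int(nrow(iv), 1L, prob = w)
  iv$start[i] + sample.int(w[i], 1L) - 1L
}

# Every (lncRNA, closest gene) pair satisfying the positional criterion whose
# members both carry planted effects in the same comparison.
expected_pairs_from_effects <- function(genome, effects_long) {
  empty <- tibble(lnc_id = character(), gene_id = character(),
                  comparison = character())
  if (is.null(genome)) return(empty)
  ann <- genome$truth$annotation %>%
    filter(!is.na(.data$closest_gene),
           .data$body_overlaps_gene | .data$category != "intergenic")
  if (nrow(ann) == 0L || nrow(effects_long) == 0L) return(empty)
  ann %>%
    select("lnc_id", gene_id = "closest_gene") %>%
    inner_join(effects_long %>% select(lnc_id = "feature_id", "comparison"),
               by = "lnc_id") %>%
    semi_join(effects_long %>% select(gene_id = "feature_id", "comparison"),
              by = c("gene_id", "comparison")) %>%
    arrange(.data$comparison, .data$lnc_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
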