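test_that("a pair needs both members significant; concordance is reported", {
  genes <- make_gene("G", "chr1", 100, 500, "+",
                     exons = list(c(100, 200), c(400, 500)), cds = c(150, 450))
  lncs <- make_lnc("L", "chr1", 250, 350, "+")  # intronic in G
  ann <- annotate_lncrnas(lncs, genes)
  both_up <- identify_pairs(ann,
                            fake_de("L", "c1", 2, TRUE),
                            fake_de("G", "c1", 1.5, TRUE))
  expect_equal(nrow(both_up), 1L)
  expect_equal(both_up$concordance, "same")
  expect_equal(both_up$lnc_direction, "up")
  gene_ns <- identify_pairs(ann,
                            fake_de("L", "c1", 2, TRUE),
                            fake_de("G", "c1", 1.5, FALSE))
  expect_equal(nrow(gene_ns), 0L)
  opposite <- identify_pairs(ann,
                             fake_de("L", "c1", 2, TRUE),
                             fake_de("G", "c1", -1.5, TRUE))
  expect_equal(opposite$concordance, "opposite")
  expect_error(
    identify_pairs(ann, fake_de("L", "c1", 2, TRUE),
                   fake_de("G", "c2", 1, TRUE), "c1"),
    "absent"
  )
})

test_that("emitted pairs equal an exhaustive double loop applying both criteria", {
  cfg <- sim_config(n_genes = 30, n_lncrnas = 100, n_pairs = 30, seed = 31)
  study <- simulate_study(cfg)
  expr_pcg <- dplyr::filter(study$expr, feature_id %in% study$genes$gene_id)
  expr_lnc <- dplyr::filter(study$expr, feature_id %in% study$lncs$lnc_id)
  de_pcg <- run_de(expr_pcg, study$groups, cfg$comparisons,
                   features = expressed_features(expr_pcg, study$groups))
  de_lnc <- run_de(expr_lnc, study$groups, cfg$comparisons,
                   features = expressed_features(expr_lnc, study$groups))
  ann <- study$truth$annotation
  got <- identify_pairs(ann, de_lnc, de_pcg)
  ref <- oracle_pairs(study$lncs, study$genes, ann, de_lnc, de_pcg,
                      sort(cfg$comparisons$name))
  expect_equal(
    as.data.frame(dplyr::select(got, lnc_id, gene_id, comparison)),
    as.data.frame(ref)
  )
  # determinism: identical inputs give identical tables
  expect_identical(got, identify_pairs(ann, de_lnc, de_pcg))
})

test_that("the counting chain is exact on a hand-built fixture", {
  # 20 DE lncRNAs: 6 intergenic without overlap, 14 annotated; of the
  # annotated, 9 have a significant closest gene -> chain (20, 14, 9)
  n <- 20
  lnc_ids <- sprintf("L%02d", 1:n)
  gene_ids <- sprintf("G%02d", 1:n)
  ann <- structure(tibble::tibble(
    lnc_id = lnc_ids,
    closest_gene = gene_ids,
    distance = 0L,
    category = factor(c(rep("intergenic", 6), rep("intron", 14)),
                      levels = annotation_categories()),
    body_overlaps_gene = FALSE
  ), class = c("lnc_annotation", class(tibble::tibble())))
  lnc_de <- fake_de(lnc_ids, "c1", 2, TRUE)
  gene_sig <- c(rep(TRUE, 6), rep(TRUE, 9), rep(FALSE, 5))
  gene_de <- fake_de(gene_ids, "c1", 1, gene_sig)
  chain <- pair_counting_chain(ann, lnc_de, gene_de)
  expect_equal(chain$n_de_lncrnas, 20L)
  expect_equal(chain$n_annotated, 14L)
  expect_equal(chain$n_pairs, 9L)
})

test_that("every DE lncRNA intergenic gives chain (k, 0, 0)", {
  ann <- structure(tibble::tibble(
    lnc_id = sprintf("L%d", 1:5),
    closest_gene = "G1",
    distance = 99999L,
    category = factor("intergenic", levels = annotation_categories()),
    body_overlaps_gene = FALSE
  ), class = c("lnc_annotation", class(tibble::tibble())))
  chain <- pair_counting_chain(ann, fake_de(sprintf("L%d", 1:5), "c1", 2, TRUE),
                               fake_de("G1", "c1", 2, TRUE))
  expect_equal(unlist(chain[, -1]), c(n_de_lncrnas = 5L, n_annotated = 0L, n_pairs = 0L))
})

test_that("the chain is monotone non-increasing on simulated runs", {
  for (seed in c(2, 4)) {
    cfg <- sim_config(seed = seed)
    study <- simulate_study(cfg)
    expr_pcg <- dplyr::filter(study$expr, feature_id %in% study$genes$gene_id)
    expr_lnc <- dplyr::filter(study$expr, feature_id %in% study$lncs$lnc_id)
    de_pcg <- run_de(expr_pcg, study$groups, cfg$comparisons,
                     features = expressed_features(expr_pcg, study$groups))
    de_lnc <- run_de(expr_lnc, study$groups, cfg$comparisons,
                     features = expressed_features(expr_lnc, study$groups))
    chain <- pair_counting_chain(study$truth$annotation, de_lnc, de_pcg)
    expect_true(all(chain$n_de_lncrnas >= chain$n_annotated))
    expect_true(all(chain$n_annotated >= chain$n_pairs))
  }
})
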