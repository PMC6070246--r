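# reference gene used across categorization cases:
# + strand, exons [100,200) and [400,500), CDS [150,450)
ref_gene <- function() {
  make_gene("G", "chr1", 100, 500, "+",
            exons = list(c(100, 200), c(400, 500)), cds = c(150, 450))
}

test_that("closest gene minimizes anchor-to-span distance with deterministic ties", {
  genes <- bind_genes(
    make_gene("A", "chr1", 1000, 2000, "+"),
    make_gene("B", "chr1", 3000, 4000, "+")
  )
  idx <- build_index(genes)
  inside <- closest_pcg(make_lnc("l1", "chr1", 1500, 1600, "+"), idx)
  expect_equal(inside$closest_gene, "A")
  expect_equal(inside$distance, 0L)
  between <- closest_pcg(make_lnc("l2", "chr1", 2299, 2400, "+"), idx)  # 300 vs 701 bp
  expect_equal(between$closest_gene, "A")
  none <- closest_pcg(make_lnc("l3", "chrM", 10, 20, "+"), idx)
  expect_true(is.na(none$closest_gene))
  # equidistant tie breaks to the lexicographically smaller id
  tie_idx <- build_index(bind_genes(
    make_gene("B", "chr9", 0, 100, "+"),
    make_gene("A", "chr9", 199, 300, "+")
  ))
  tie <- closest_pcg(make_lnc("l4", "chr9", 149, 160, "+"), tie_idx)
  expect_equal(tie$closest_gene, "A")
})

test_that("random loci get the same closest gene as a brute-force scan", {
  withr::local_seed(41)
  genes <- bind_genes(purrr::map(1:40, function(i) {
    s <- sample.int(200000, 1)
    make_gene(sprintf("G%02d", i), sample(c("chr1", "chr2"), 1),
              s, s + sample.int(8000, 1), sample(c("+", "-"), 1))
  }))
  idx <- build_index(genes)
  lncs <- bind_lncs(purrr::map(1:100, function(i) {
    s <- sample.int(210000, 1)
    make_lnc(sprintf("L%03d", i), sample(c("chr1", "chr2"), 1),
             s, s + sample.int(2000, 1), sample(c("+", "-"), 1))
  }))
  got <- closest_pcg(lncs, idx)
  for (i in seq_len(nrow(lncs))) {
    ref <- oracle_closest(lncs$chrom[i], lncs$anchor[i], genes)
    expect_equal(got$closest_gene[got$lnc_id == lncs$lnc_id[i]], ref$gene_id)
    expect_equal(got$distance[got$lnc_id == lncs$lnc_id[i]], ref$signed)
  }
})

test_that("anchor position decides the category", {
  g <- ref_gene()
  expect_equal(categorize_anchor(300, g), "intron")
  expect_equal(categorize_anchor(120, g), "utr5")
  expect_equal(categorize_anchor(470, g), "utr3")
  expect_equal(categorize_anchor(160, g), "exon")
  expect_error(categorize_anchor(300, g, upstream_window = 0), "positive")
})

test_that("upstream/downstream windows are inclusive at 5000 and 1000 bp", {
  g <- ref_gene()
  expect_equal(categorize_anchor(100 - 5000, g), "upstream")
  expect_equal(categorize_anchor(100 - 5001, g), "intergenic")
  expect_equal(categorize_anchor(499 + 1000, g), "downstream")
  expect_equal(categorize_anchor(499 + 1001, g), "intergenic")
  expect_equal(categorize_anchor(99, g), "upstream")
  expect_equal(categorize_anchor(500, g), "downstream")
})

test_that("minus-strand genes mirror the plus-strand categories", {
  g <- ref_gene()
  L <- 10000L
  gm <- mirror_genes(g, L)
  for (anchor in c(300, 120, 470, 160, 99, 500, 100 - 5000, 100 - 5001,
                   499 + 1000, 499 + 1001)) {
    expect_equal(
      categorize_anchor(L - 1L - anchor, gm),
      categorize_anchor(anchor, g),
      label = sprintf("mirrored anchor %d", anchor)
    )
  }
})

test_that("annotation recovers planted categories and matches the per-base oracle", {
  cfg <- sim_config(n_genes = 20, n_lncrnas = 100, n_pairs = 5, seed = 19)
  study <- simulate_genome(cfg)
  ann <- study$truth$annotation
  expect_equal(nrow(ann), 100L)
  merged <- dplyr::inner_join(ann, study$truth$lnc, by = "lnc_id")
  expect_equal(as.character(merged$category.x), merged$category.y)
  for (i in seq_len(nrow(study$lncs))) {
    l <- study$lncs[i, ]
    expect_equal(
      as.character(ann$category[ann$lnc_id == l$lnc_id]),
      oracle_categorize(l$chrom, l$anchor, study$genes),
      label = l$lnc_id
    )
  }
  expect_equal(nrow(annotate_lncrnas(study$lncs[0, ], study$genes)), 0L)
})

test_that("category distributions count and round as expected", {
  ann <- annotate_lncrnas(
    bind_lncs(
      make_lnc("l1", "chr1", 300, 350, "+"),   # intron
      make_lnc("l2", "chr1", 320, 360, "+"),   # intron
      make_lnc("l3", "chr1", 470, 490, "+"),   # utr3
      make_lnc("l4", "chr1", 50000, 50100, "+") # intergenic
    ),
    ref_gene()
  )
  cd <- category_distribution(ann)
  expect_equal(cd$n[cd$category == "intron"], 2L)
  expect_equal(cd$percent[cd$category == "intron"], 50L)
  expect_equal(cd$percent[cd$category == "utr3"], 25L)
  expect_equal(cd$percent[cd$category == "intergenic"], 25L)
  expect_equal(sum(cd$n), 4L)
  empty <- category_distribution(ann, subset = character())
  expect_true(all(empty$n == 0L))
  expect_error(category_distribution(ann, subset = "ghost"), "unknown")
})

test_that("planted category proportions are recovered exactly", {
  cfg <- sim_config(n_genes = 30, n_lncrnas = 500, n_pairs = 10, seed = 23)
  study <- simulate_genome(cfg)
  cd <- category_distribution(study$truth$annotation)
  quota <- round(500 * cfg$category_proportions[as.character(cd$category)])
  expect_equal(cd$n, as.integer(quota), ignore_attr = TRUE)
  expect_equal(cd$percent[cd$category == "intron"], 44L)
  expect_equal(cd$percent[cd$category == "intergenic"], 26L)
  expect_equal(cd$percent[cd$category == "utr3"], 16L)
})

test_that("widening the upstream window only converts intergenic to upstream", {
  cfg <- sim_config(n_genes = 20, n_lncrnas = 120, n_pairs = 0, seed = 29)
  study <- simulate_genome(cfg)
  narrow <- annotate_lncrnas(study$lncs, study$genes, upstream_window = 5000)
  wide <- annotate_lncrnas(study$lncs, study$genes, upstream_window = 12000)
  changed <- as.character(narrow$category) != as.character(wide$category)
  expect_true(all(as.character(narrow$category[changed]) == "intergenic"))
  expect_true(all(as.character(wide$category[changed]) == "upstream"))
  expect_true(all(narrow$lnc_id[narrow$category == "upstream"] %in%
                    wide$lnc_id[wide$category == "upstream"]))
})
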