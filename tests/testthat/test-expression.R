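two_group_expr <- function(m, groups_of_cols) {
  expr <- dplyr::bind_cols(
    tibble::tibble(feature_id = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
  groups <- tibble::tibble(sample_id = colnames(m), group = groups_of_cols)
  list(expr = expr, groups = groups)
}

test_that("group means are arithmetic means per group", {
  m <- rbind(f1 = c(2, 4, 10), f2 = c(0, 0, 0))
  colnames(m) <- c("s1", "s2", "s3")
  d <- two_group_expr(m, c("A", "A", "B"))
  gm <- group_means(d$expr, d$groups)
  expect_equal(gm$mean_fpkm[gm$feature_id == "f1" & gm$group == "A"], 3)
  expect_equal(gm$mean_fpkm[gm$feature_id == "f1" & gm$group == "B"], 10)
  expect_equal(gm$mean_fpkm[gm$feature_id == "f2"], c(0, 0))
})

test_that("group means match a per-feature loop on random data", {
  withr::local_seed(21)
  m <- matrix(stats::rexp(20 * 7), nrow = 20,
              dimnames = list(sprintf("f%02d", 1:20), sprintf("s%d", 1:7)))
  grp <- c("A", "A", "B", "B", "B", "C", "C")
  d <- two_group_expr(m, grp)
  gm <- group_means(d$expr, d$groups)
  for (f in rownames(m)) {
    for (g in unique(grp)) {
      expect_equal(gm$mean_fpkm[gm$feature_id == f & gm$group == g],
                   mean(m[f, grp == g]))
    }
  }
})

test_that("presence calls use 'at least cutoff in some group', boundary inclusive", {
  gm <- tibble::tibble(
    feature_id = rep(c("a", "b", "c"), each = 3),
    group = rep(c("g1", "g2", "g3"), 3),
    mean_fpkm = c(0.2, 0.9, 0.4,  0.2, 1.0, 0.4,  0, 37.29, 0)
  )
  e <- is_expressed(gm)
  expect_false(e$expressed[e$feature_id == "a"])
  expect_true(e$expressed[e$feature_id == "b"])   # boundary value 1.0
  expect_true(e$expressed[e$feature_id == "c"])   # strongly induced gene
})

test_that("the built-in test agrees with stats::t.test per feature", {
  withr::local_seed(33)
  m <- matrix(stats::rlnorm(50 * 7, 2, 1), nrow = 50,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("s%d", 1:7)))
  grp <- c(rep("ctl", 3), rep("trt", 4))
  d <- two_group_expr(m, grp)
  de <- run_de(d$expr, d$groups,
               tibble::tibble(name = "c", control = "ctl", treated = "trt"))
  lm2 <- log2(m + 1)
  for (f in rownames(m)) {
    ref <- stats::t.test(lm2[f, grp == "trt"], lm2[f, grp == "ctl"])
    expect_equal(de$p_value[de$feature_id == f], ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance features are never significant", {
  m <- rbind(flat = c(5, 5, 5, 5, 5, 5))
  colnames(m) <- sprintf("s%d", 1:6)
  d <- two_group_expr(m, rep(c("A", "B"), each = 3))
  de <- run_de(d$expr, d$groups,
               tibble::tibble(name = "c", control = "A", treated = "B"))
  expect_equal(de$log2fc, 0)
  expect_equal(de$p_value, 1)
  expect_false(de$significant)
  expect_equal(de$direction, "none")
})

test_that("groups of one sample and missing values are rejected", {
  m <- rbind(f = c(1, 2, 3))
  colnames(m) <- sprintf("s%d", 1:3)
  d <- two_group_expr(m, c("A", "B", "B"))
  expect_error(
    run_de(d$expr, d$groups, tibble::tibble(name = "c", control = "A", treated = "B")),
    "'A'"
  )
  m2 <- rbind(f = c(1, NA, 3, 4))
  colnames(m2) <- sprintf("s%d", 1:4)
  d2 <- two_group_expr(m2, c("A", "A", "B", "B"))
  expect_error(
    run_de(d2$expr, d2$groups, tibble::tibble(name = "c", control = "A", treated = "B")),
    "missing"
  )
})

test_that("swapping control and treated negates log2fc and keeps p", {
  withr::local_seed(55)
  m <- matrix(stats::rlnorm(30 * 6, 2, 1), nrow = 30,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%d", 1:6)))
  d <- two_group_expr(m, rep(c("A", "B"), each = 3))
  fwd <- run_de(d$expr, d$groups, tibble::tibble(name = "c", control = "A", treated = "B"))
  rev <- run_de(d$expr, d$groups, tibble::tibble(name = "c", control = "B", treated = "A"))
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$log2fc, -rev$log2fc)
})

test_that("a strong planted effect is detected as up in nearly all replicates", {
  withr::local_seed(77)
  n_rep <- 200
  baseline <- 10
  ctl <- matrix(baseline * 2^stats::rnorm(n_rep * 4, 0, 0.25), nrow = n_rep)
  trt <- matrix(baseline * 2^(3 + stats::rnorm(n_rep * 4, 0, 0.25)), nrow = n_rep)
  m <- cbind(ctl, trt)
  rownames(m) <- sprintf("f%03d", 1:n_rep)
  colnames(m) <- sprintf("s%d", 1:8)
  d <- two_group_expr(m, rep(c("A", "B"), each = 4))
  de <- run_de(d$expr, d$groups, tibble::tibble(name = "c", control = "A", treated = "B"))
  expect_gte(mean(de$significant & de$direction == "up"), 0.95)
})

test_that("detection rate is monotone in the planted effect size", {
  withr::local_seed(99)
  rate <- vapply(c(0, 1, 2, 3), function(eff) {
    n_rep <- 300
    ctl <- matrix(10 * 2^stats::rnorm(n_rep * 4, 0, 0.25), nrow = n_rep)
    trt <- matrix(10 * 2^(eff + stats::rnorm(n_rep * 4, 0, 0.25)), nrow = n_rep)
    m <- cbind(ctl, trt)
    rownames(m) <- sprintf("f%03d", 1:n_rep)
    colnames(m) <- sprintf("s%d", 1:8)
    d <- two_group_expr(m, rep(c("A", "B"), each = 4))
    mean(run_de(d$expr, d$groups,
                tibble::tibble(name = "c", control = "A", treated = "B"))$significant)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
})

test_that("external DE tables import with significance recomputed", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    feature_id = c("geneX", "geneY", "geneZ"),
    comparison = "CV_CO_vs_CV_BDE-47",
    log2fc = c(2.0, -1.0, 0.5),
    p_value = c(0.001, 0.05, 0.2)
  ), f)
  de <- import_de_table(f, alpha = 0.05)
  expect_equal(nrow(de), 3L)
  expect_equal(de$direction[de$feature_id == "geneX"], "up")
  # p exactly at alpha is NOT significant: strict inequality
  expect_false(de$significant[de$feature_id == "geneY"])
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(de, f2)
  expect_equal(as.data.frame(import_de_table(f2)), as.data.frame(de))
})

test_that("DE import requires the schema columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(feature_id = "x", log2fc = 1), f)
  expect_error(import_de_table(f), "missing column")
})

test_that("the not-expressed/stable/differential partition is conservative", {
  m <- rbind(
    lo1 = rep(0.1, 6), lo2 = rep(0.2, 6), lo3 = rep(0, 6), lo4 = rep(0.5, 6),
    hi1 = rep(5, 6), hi2 = rep(8, 6), hi3 = rep(2, 6), hi4 = rep(9, 6),
    sig1 = c(2, 2, 2, 9, 9, 9), sig2 = c(9, 9, 9, 2, 2, 2)
  )
  colnames(m) <- sprintf("s%d", 1:6)
  d <- two_group_expr(m, rep(c("A", "B"), each = 3))
  de <- fake_de(c("sig1", "sig2"), "c", c(2, -2), TRUE)
  part <- partition_features(d$expr, d$groups, de)
  expect_equal(glance(part)$n_not_expressed, 4L)
  expect_equal(glance(part)$n_stable, 4L)
  expect_equal(sort(part$differential), c("sig1", "sig2"))
  # empty DE results: everything expressed is stable
  part0 <- partition_features(d$expr, d$groups, fake_de(character(), character(), numeric(), logical()))
  expect_length(part0$differential, 0L)
  expect_equal(length(part0$stable), 6L)
  # conservation on a random fixture
  withr::local_seed(13)
  s <- simulate_study(sim_config(n_genes = 40, n_lncrnas = 0, n_pairs = 0, seed = 13))
  expr <- s$expr
  de2 <- run_de(expr, s$groups, s$config$comparisons,
                features = expressed_features(expr, s$groups))
  p <- partition_features(expr, s$groups, de2)
  expect_setequal(c(p$not_expressed, p$stable, p$differential), expr$feature_id)
  expect_length(intersect(p$stable, p$differential), 0L)
  expect_length(intersect(p$not_expressed, p$stable), 0L)
  expect_error(
    partition_features(d$expr, d$groups, fake_de("ghost", "c", 1, TRUE)),
    "absent"
  )
})

test_that("fold changes format as fold-increase or percent decrease", {
  expect_equal(format_fold_change(4, 1), "75%")
  expect_equal(format_fold_change(1, 2), "2.00")
  expect_equal(format_fold_change(5, 0), "100%")
  expect_equal(format_fold_change(1, 37.3), "37.26")
})
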