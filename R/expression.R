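#' Per-group mean FPKM
#'
#' @param expr Expression tibble: `feature_id` column followed by one numeric
#'   FPKM column per sample (non-negative, no missing values).
#' @param groups Tibble mapping `sample_id` to `group`; every sample column of
#'   `expr` must appear.
#' @return Long tibble with columns `feature_id`, `group`, `mean_fpkm`
#'   (arithmetic mean over the group's samples).
#' @export
group_means <- function(expr, groups) {
  m <- expr_matrix(expr, groups)
  grp <- groups$group[match(colnames(m), groups$sample_id)]
  out <- purrr::map(sort(unique(grp)), function(g) {
    cols <- m[, grp == g, drop = FALSE]
    tibble(feature_id = rownames(m), group = g, mean_fpkm = unname(rowMeans(cols)))
  }) %>% bind_rows()
  arrange(out, .data$feature_id, .data$group)
}

#' Presence call from group means
#'
#' A feature counts as expressed when its mean FPKM reaches `cutoff` in at
#' least one group (the complement of "mean FPKM below `cutoff` in all
#' groups"; the boundary value itself counts as expressed).
#'
#' @param means Long tibble from [group_means()].
#' @param cutoff Mean-FPKM presence threshold (default 1).
#' @return Tibble with columns `feature_id` and logical `expressed`.
#' @export
is_expressed <- function(means, cutoff = 1) {
  means %>%
    group_by(.data$feature_id) %>%
    summarise(expressed = max(.data$mean_fpkm) >= cutoff, .groups = "drop")
}

#' Feature ids passing the presence filter
#'
#' @inheritParams group_means
#' @inheritParams is_expressed
#' @return Sorted character vector of expressed feature ids.
#' @export
expressed_features <- function(expr, groups, cutoff = 1) {
  e <- is_expressed(group_means(expr, groups), cutoff)
  sort(e$feature_id[e$expressed])
}

#' The four treated-vs-vehicle contrasts of the CV/GF study design
#'
#' Within each enterotype (conventional CV, germ-free GF), each PBDE-exposed
#' group is contrasted against the corn-oil vehicle group of the same
#' enterotype.
#'
#' @return Tibble with columns `name`, `control`, `treated`.
#' @export
default_comparisons <- function() {
  tibble(
    name = c("CV_CO_vs_CV_BDE-47", "CV_CO_vs_CV_BDE-99",
             "GF_CO_vs_GF_BDE-47", "GF_CO_vs_GF_BDE-99"),
    control = c("CV_CO", "CV_CO", "GF_CO", "GF_CO"),
    treated = c("CV_BDE-47", "CV_BDE-99", "GF_BDE-47", "GF_BDE-99")
  )
}

#' Two-group differential expression per contrast
#'
#' For every feature, a Welch two-sample t-test on `log2(FPKM + 1)` between
#' the treated and control groups, with the fold change summarised as
#' `log2fc = log2((treated_mean + eps) / (control_mean + eps))` on the raw
#' FPKM group means. Features with zero variance in both groups are never
#' called significant (their p-value is reported as 1). Significance is
#' `p < alpha`, strict, on the raw or Benjamini-Hochberg-adjusted p-value
#' according to `adjust`; each comparison is tested and (optionally) adjusted
#' independently.
#'
#' @inheritParams group_means
#' @param comparisons Tibble with columns `name`, `control`, `treated` (one
#'   row per contrast), e.g. [default_comparisons()].
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (raw p, default) or `"BH"`.
#' @param features Optional character vector restricting the test to these
#'   feature ids (typically the presence-filtered set).
#' @param eps Pseudocount added to both group means in the fold-change ratio
#'   (default 0.001).
#' @return Tibble with one row per feature and comparison: `feature_id`,
#'   `comparison`, `control_mean`, `treated_mean`, `log2fc`, `p_value`,
#'   `adjusted_p` (`NA` when `adjust = "none"`), `significant`, `direction`
#'   (`"up"`/`"down"`/`"none"`).
#' @export
run_de <- function(expr, groups, comparisons = default_comparisons(),
                   alpha = 0.05, adjust = c("none", "BH"),
                   features = NULL, eps = 0.001) {
  adjust <- match.arg(adjust)
  m <- expr_matrix(expr, groups)
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(m))
    if (length(missing) > 0L) {
      abort(sprintf("feature '%s' not present in the expression matrix", missing[1]))
    }
    m <- m[rownames(m) %in% features, , drop = FALSE]
  }
  grp <- groups$group[match(colnames(m), groups$sample_id)]
  purrr::pmap(comparisons, function(name, control, treated, ...) {
    for (g in c(control, treated)) {
      n_g <- sum(grp == g)
      if (n_g == 0L) abort(sprintf("comparison '%s': group '%s' absent from the matrix", name, g))
      if (n_g < 2L) abort(sprintf("comparison '%s': group '%s' has fewer than 2 samples", name, g))
    }
    ctl <- m[, grp == control, drop = FALSE]
    trt <- m[, grp == treated, drop = FALSE]
    p <- welch_p(log2(ctl + 1), log2(trt + 1))
    control_mean <- unname(rowMeans(ctl))
    treated_mean <- unname(rowMeans(trt))
    log2fc <- log2((treated_mean + eps) / (control_mean + eps))
    adjusted_p <- if (adjust == "BH") p.adjust(p, method = "BH") else rep(NA_real_, length(p))
    p_used <- if (adjust == "BH") adjusted_p else p
    significant <- p_used < alpha
    tibble(
      feature_id = rownames(m),
      comparison = name,
      control_mean = control_mean,
      treated_mean = treated_mean,
      log2fc = log2fc,
      p_value = p,
      adjusted_p = adjusted_p,
      significant = significant,
      direction = dplyr::case_when(
        significant & log2fc > 0 ~ "up",
        significant & log2fc < 0 ~ "down",
        .default = "none"
      )
    )
  }) %>%
    bind_rows() %>%
    arrange(.data$comparison, .data$feature_id)
}

#' Import externally computed differential-expression tables
#'
#' Lets results from an external caller (e.g. Cuffdiff) drive the downstream
#' pairing and set-partition stages. Significance is recomputed against
#' `alpha` so the pipeline's strict `p < alpha` rule applies uniformly.
#'
#' @param path TSV with columns `feature_id`, `comparison`, `log2fc` (or
#'   `fold_change`, which is log2-transformed on import), `p_value`, and
#'   optionally `control_mean`, `treated_mean`, `adjusted_p`.
#' @inheritParams run_de
#' @return A tibble in the same shape as [run_de()].
#' @export
import_de_table <- function(path, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  de <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"log2fc" %in% names(de) && "fold_change" %in% names(de)) {
    de$log2fc <- log2(de$fold_change)
    de$fold_change <- NULL
  }
  needed <- c("feature_id", "comparison", "log2fc", "p_value")
  missing <- setdiff(needed, names(de))
  if (length(missing) > 0L) {
    abort(sprintf("DE table '%s' is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  for (col in c("control_mean", "treated_mean", "adjusted_p")) {
    if (!col %in% names(de)) de[[col]] <- NA_real_
    de[[col]] <- as.numeric(de[[col]])
  }
  if (adjust == "BH") {
    de <- de %>%
      group_by(.data$comparison) %>%
      mutate(adjusted_p = p.adjust(.data$p_value, method = "BH")) %>%
      ungroup()
  }
  p_used <- if (adjust == "BH") de$adjusted_p else de$p_value
  de %>%
    mutate(
      significant = p_used < alpha,
      direction = dplyr::case_when(
        .data$significant & .data$log2fc > 0 ~ "up",
        .data$significant & .data$log2fc < 0 ~ "down",
        .default = "none"
      )
    ) %>%
    select("feature_id", "comparison", "control_mean", "treated_mean",
           "log2fc", "p_value", "adjusted_p", "significant", "direction") %>%
    arrange(.data$comparison, .data$feature_id)
}

#' Write a differential-expression table to TSV
#'
#' @param de Tibble from [run_de()] or [import_de_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(de, path)
  invisible(path)
}

#' Partition features into not-expressed / stable / differential
#'
#' Mirrors the study's pie-chart structure: a feature is *not expressed* when
#' its mean FPKM stays below the presence cutoff in every group; among
#' expressed features, those significant in at least one comparison are
#' *differential* and the remainder *stable*. The three sets are disjoint and
#' cover the matrix.
#'
#' @inheritParams group_means
#' @param de DE tibble covering the expressed features over the comparisons.
#' @param cutoff Presence cutoff (default 1).
#' @return Object of class `expr_partition`: a list with character-vector
#'   elements `not_expressed`, `stable`, `differential`. Has [tidy()],
#'   [glance()] and [ggplot2::autoplot()] methods.
#' @export
partition_features <- function(expr, groups, de, cutoff = 1) {
  all_ids <- expr$feature_id
  stray <- setdiff(de$feature_id, all_ids)
  if (length(stray) > 0L) {
    abort(sprintf("DE results contain feature '%s' absent from the matrix", stray[1]))
  }
  expressed <- expressed_features(expr, groups, cutoff)
  sig <- unique(de$feature_id[de$significant])
  differential <- sort(intersect(expressed, sig))
  structure(
    list(
      not_expressed = sort(setdiff(all_ids, expressed)),
      stable = sort(setdiff(expressed, differential)),
      differential = differential
    ),
    class = "expr_partition"
  )
}

#' Dual fold-change presentation
#'
#' Induction is reported as an x.xx fold-increase and repression as a percent
#' decrease, the two-column presentation used for top-regulated gene tables.
#' With `ratio = (treated + eps) / (control + eps)`: ratios at or above 1
#' format as the ratio to two decimals; ratios below 1 format as
#' `round((1 - ratio) * 100)` percent decrease, so complete abolition of an
#' expressed gene reads "100%".
#'
#' @param control_mean,treated_mean Non-negative mean FPKM vectors.
#' @param eps Pseudocount (default 0.001).
#' @return Character vector like `"37.29"` (fold-increase) or `"82%"`
#'   (decrease).
#' @export
format_fold_change <- function(control_mean, treated_mean, eps = 0.001) {
  r <- fold_change_ratio(control_mean, treated_mean, eps)
  ifelse(r >= 1, sprintf("%.2f", r), sprintf("%d%%", as.integer(round((1 - r) * 100))))
}

#' @rdname format_fold_change
#' @export
fold_change_ratio <- function(control_mean, treated_mean, eps = 0.001) {
  (treated_mean + eps) / (control_mean + eps)
}

# -- internals ----------------------------------------------------------------

# expr tibble -> numeric matrix with feature_id rownames, validated against
# the sample->group map.
expr_matrix <- function(expr, groups) {
  if (!"feature_id" %in% names(expr)) abort("expression table needs a 'feature_id' column")
  if (anyDuplicated(expr$feature_id)) abort("duplicate feature_id in expression table")
  samples <- setdiff(names(expr), "feature_id")
  unmapped <- setdiff(samples, groups$sample_id)
  if (length(unmapped) > 0L) {
    abort(sprintf("sample '%s' has no group assignment", unmapped[1]))
  }
  m <- as.matrix(expr[, samples, drop = FALSE])
  if (!is.numeric(m)) abort("expression values must be numeric")
  if (anyNA(m)) abort("expression matrix contains missing values")
  if (any(m < 0)) abort("expression values must be non-negative (FPKM)")
  rownames(m) <- expr$feature_id
  m
}

# Vectorized Welch two-sample test per row; returns two-sided p-values.
# Rows with zero variance in both groups get p = 1.
welch_p <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, nrow(x))
  ok <- se2 > 0
  tstat <- (m2[ok] - m1[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  unname(p)
}
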