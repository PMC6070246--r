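#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an expression partition
#'
#' @param x An `expr_partition`.
#' @param ... Unused.
#' @return Tibble with columns `feature_id` and `status`
#'   (`not_expressed`/`stable`/`differential`).
#' @export
tidy.expr_partition <- function(x, ...) {
  tibble(
    feature_id = c(x$not_expressed, x$stable, x$differential),
    status = rep(c("not_expressed", "stable", "differential"),
                 c(length(x$not_expressed), length(x$stable),
                   length(x$differential)))
  ) %>% arrange(.data$feature_id)
}

#' @rdname tidy.expr_partition
#' @return For `glance()`: a one-row tibble of set sizes.
#' @export
glance.expr_partition <- function(x, ...) {
  tibble(
    n_total = length(x$not_expressed) + length(x$stable) + length(x$differential),
    n_not_expressed = length(x$not_expressed),
    n_stable = length(x$stable),
    n_differential = length(x$differential)
  )
}

#' Tidy a Venn partition
#'
#' @param x A `venn_partition`.
#' @param ... Unused.
#' @return Tibble with `region`, `n_sets`, `n` and `ids` (comma-collapsed).
#' @export
tidy.venn_partition <- function(x, ...) {
  tibble(
    region = x$region,
    n_sets = x$n_sets,
    n = x$n,
    ids = vapply(x$ids, paste, "", collapse = ",")
  )
}

#' @rdname tidy.venn_partition
#' @return For `glance()`: input set count, non-empty regions and union size.
#' @export
glance.venn_partition <- function(x, ...) {
  tibble(
    n_sets = length(attr(x, "set_names")),
    n_regions = nrow(x),
    n_regions_nonempty = sum(x$n > 0),
    n_union = sum(x$n)
  )
}

#' @export
print.expr_partition <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<expr_partition> %d features: %d not expressed, %d stable, %d differential\n",
    g$n_total, g$n_not_expressed, g$n_stable, g$n_differential
  ))
  invisible(x)
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study> %d PCGs, %d lncRNAs, %d samples in %d groups, %d planted pairs (seed %d)\n",
    nrow(x$genes), nrow(x$lncs), nrow(x$groups),
    length(unique(x$groups$group)), nrow(x$truth$pairs),
    as.integer(x$config$seed)
  ))
  invisible(x)
}

#' @export
print.lnc_report <- function(x, ...) {
  gp <- glance(x$partition$pcg)
  gl <- glance(x$partition$lnc)
  cat("<lnc_report>\n")
  cat(sprintf("  PCGs:    %d (%d not expressed / %d stable / %d differential)\n",
              gp$n_total, gp$n_not_expressed, gp$n_stable, gp$n_differential))
  cat(sprintf("  lncRNAs: %d (%d not expressed / %d stable / %d differential)\n",
              gl$n_total, gl$n_not_expressed, gl$n_stable, gl$n_differential))
  cat(sprintf("  lncRNA-PCG pairs: %d\n", nrow(x$pairs)))
  invisible(x)
}
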