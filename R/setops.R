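#' Venn partition of differential calls across comparisons
#'
#' Assigns every feature in the union of the input sets to exactly one region:
#' the subset of comparisons it belongs to. With four comparisons this yields
#' the 15 regions of a four-set Venn diagram. Regions are keyed by the subset
#' (set names sorted alphabetically), so the partition does not depend on the
#' order the sets are supplied in.
#'
#' @param sets Named list of 2 to 6 character vectors (feature ids per
#'   comparison).
#' @return Tibble of class `venn_partition` with one row per non-empty subset
#'   of set names: `region` (names joined by `"&"`), `n_sets` (subset size),
#'   `ids` (list-column) and `n`. All `2^k - 1` regions are present, empty
#'   ones with `n = 0`.
#' @export
venn_partition <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("sets must be a named list")
  }
  k <- length(sets)
  if (k < 2L || k > 6L) abort("venn_partition supports 2 to 6 sets")
  nm <- names(sets)
  sets <- purrr::map(sets, unique)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- matrix(
    vapply(sets, function(s) universe %in% s, logical(length(universe))),
    nrow = length(universe), dimnames = list(NULL, nm)
  )
  profile <- if (length(universe) == 0L) character(0) else
    apply(membership, 1L, function(row) paste(sort(nm[row]), collapse = "&"))
  subsets <- unlist(purrr::map(seq_len(k), function(size) {
    combn(sort(nm), size, FUN = paste, collapse = "&")
  }))
  by_region <- split(universe, factor(profile, levels = subsets))
  out <- tibble(
    region = subsets,
    n_sets = unname(lengths(strsplit(subsets, "&", fixed = TRUE))),
    ids = unname(purrr::map(by_region, identity)),
    n = unname(lengths(by_region))
  )
  structure(out, class = c("venn_partition", class(tibble())),
            set_names = sort(nm))
}

#' Common and comparison-unique features
#'
#' Projects the Venn partition onto its two ends: the features present in
#' every comparison, and those unique to each single comparison.
#'
#' @inheritParams venn_partition
#' @return List with `common` (sorted ids in all sets) and `unique` (named
#'   list, ids in exactly that one set).
#' @export
common_unique <- function(sets) {
  vp <- venn_partition(sets)
  all_region <- paste(sort(names(sets)), collapse = "&")
  list(
    common = vp$ids[[which(vp$region == all_region)]],
    unique = setNames(
      purrr::map(sort(names(sets)), function(nm) vp$ids[[which(vp$region == nm)]]),
      sort(names(sets))
    )
  )
}

#' Directional expression patterns across the four comparisons
#'
#' For features significant in *all* of the given comparisons, the ordered
#' vector of fold-change signs — e.g. `"+,+,+,+"` for a feature up-regulated
#' by both chemicals in both enterotypes. Four recurrent sign vectors carry
#' named aliases (see [pattern_alias()]). Features not significant in every
#' comparison are not classifiable and are omitted.
#'
#' @param de DE tibble (shape of [run_de()]).
#' @param comparisons Ordered character vector of comparison names defining
#'   the sign-vector order; default the four study contrasts in
#'   [default_comparisons()] order.
#' @return Tibble with columns `feature_id`, `pattern` (sign string) and
#'   `alias` (`NA` when the sign vector has no named alias).
#' @export
classify_patterns <- function(de, comparisons = default_comparisons()$name) {
  missing <- setdiff(comparisons, unique(de$comparison))
  if (length(missing) > 0L) {
    abort(sprintf("comparison '%s' absent from the DE results", missing[1]))
  }
  sig <- de %>%
    filter(.data$comparison %in% comparisons, .data$significant)
  if (any(sig$log2fc == 0)) {
    abort("significant feature with zero log2 fold-change: invalid DE result")
  }
  wide <- sig %>%
    mutate(sign = ifelse(.data$log2fc > 0, "+", "-")) %>%
    select("feature_id", "comparison", "sign") %>%
    tidyr::pivot_wider(names_from = "comparison", values_from = "sign")
  for (cmp in comparisons) {
    if (!cmp %in% names(wide)) wide[[cmp]] <- NA_character_
  }
  complete <- stats::complete.cases(wide[comparisons])
  wide <- wide[complete, , drop = FALSE]
  pattern <- if (nrow(wide) == 0L) character(0) else
    apply(wide[comparisons], 1L, paste, collapse = ",")
  tibble(
    feature_id = wide$feature_id,
    pattern = as.character(pattern),
    alias = pattern_alias(as.character(pattern))
  ) %>% arrange(.data$feature_id)
}

#' Named aliases for recurrent sign vectors
#'
#' With the comparisons ordered (CV BDE-47, CV BDE-99, GF BDE-47, GF BDE-99):
#' `+,+,+,+` is consistent up-regulation in both enterotypes (`Pattern1-up`);
#' `-,-,-,-` consistent down-regulation (`Pattern2-down`); `-,-,-,+` down
#' everywhere except up-regulation by BDE-99 in germ-free mice (`Pattern3`);
#' `+,+,-,-` opposite regulation between conventional (up) and germ-free
#' (down) mice (`Pattern4`).
#'
#' @param pattern Character vector of sign strings like `"+,+,-,-"`.
#' @return Character vector of aliases, `NA` where none is defined.
#' @export
pattern_alias <- function(pattern) {
  aliases <- c(
    "+,+,+,+" = "Pattern1-up",
    "-,-,-,-" = "Pattern2-down",
    "-,-,-,+" = "Pattern3",
    "+,+,-,-" = "Pattern4"
  )
  unname(aliases[pattern])
}
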