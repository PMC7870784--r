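#' Consensus miRNA-target map from multi-tool predictions
#'
#' Target-prediction tools disagree widely, so a (miRNA, gene) pair is kept
#' only when at least `k` distinct tools predict it (the default follows
#' the common "4 of 10 tools" rule). Duplicate rows from the same source
#' count once.
#'
#' @param predictions Tibble with columns `mirna`, `gene`, `source` (as
#'   from [read_predictions()]).
#' @param k Minimum number of distinct supporting sources (default 4).
#' @param n_sources Declared roster size; `k` must not exceed it. Defaults
#'   to the number of distinct sources present.
#' @return Tibble with columns `mirna`, `gene`, `n_sources`, one row per
#'   retained pair; carries `k` as an attribute.
#' @export
build_consensus <- function(predictions, k = 4, n_sources = NULL) {
  if (nrow(predictions) == 0) abort("empty prediction table")
  n_sources <- n_sources %||% dplyr::n_distinct(predictions$source)
  if (k < 1 || k > n_sources) {
    abort(sprintf("`k` must be between 1 and the roster size (%d)", n_sources))
  }
  out <- predictions |>
    mutate(mirna = normalize_mirna(.data$mirna), gene = toupper(.data$gene)) |>
    distinct(.data$mirna, .data$gene, .data$source) |>
    count(.data$mirna, .data$gene, name = "n_sources") |>
    filter(.data$n_sources >= k) |>
    arrange(.data$mirna, .data$gene)
  attr(out, "k") <- k
  out
}

#' Per-miRNA consensus target counts
#'
#' @param consensus Output of [build_consensus()].
#' @return Tibble with columns `mirna`, `n_targets`, descending.
#' @export
consensus_target_counts <- function(consensus) {
  consensus |>
    count(.data$mirna, name = "n_targets") |>
    arrange(desc(.data$n_targets), .data$mirna)
}

#' Significant miRNA-pathway targeting pairs
#'
#' For every (miRNA, pathway) combination, tests whether the miRNA's
#' consensus target set shares more genes with the pathway than expected by
#' chance, via the upper-tail hypergeometric probability on (universe `m`,
#' pathway size `j`, target-set size `n`, overlap `x`). By default the BH
#' family is the full set of miRNA x pathway tests (global FDR over the
#' reported pair list); `fdr_scope = "per_mirna"` corrects within each
#' miRNA instead. Pairs with adjusted p below `alpha` are retained;
#' miRNAs and pathways with no retained pair do not appear in the output.
#'
#' @param consensus Consensus target map from [build_consensus()].
#' @param collection Pathway collection of the (risk) pathways to test.
#' @param universe Optional explicit universe; defaults to the union of the
#'   collection's genes. Target genes outside the universe are excluded
#'   from `n` and `x`.
#' @param m Optional fixed universe size (no gene dropping).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param fdr_scope `"global"` (default) or `"per_mirna"`.
#' @param keep_all If `TRUE`, return every tested combination with a
#'   `significant` flag.
#' @return Tibble with columns `mirna`, `pathway`, `x`, `n`, `j`, `m`,
#'   `p_value`, `p_adjust`, sorted by `p_adjust` then (mirna, pathway).
#' @export
mirna_pathway_enrichment <- function(consensus, collection, universe = NULL,
                                     m = NULL, alpha = 0.01,
                                     fdr_scope = c("global", "per_mirna"),
                                     keep_all = FALSE) {
  fdr_scope <- match.arg(fdr_scope)
  if (nrow(collection) == 0) abort("pathway collection is empty")
  if (nrow(consensus) == 0) abort("consensus target map is empty")
  sets <- restrict_collection(collection, universe)
  if (is.null(m)) {
    uni <- if (is.null(universe)) pathway_universe(collection)
    else unique(toupper(universe))
    m_size <- length(uni)
    targets <- filter(consensus, .data$gene %in% uni)
  } else {
    m_size <- as.integer(m)
    targets <- consensus
  }
  if (nrow(targets) == 0) abort("no consensus targets inside the universe")

  n_by_mirna <- count(targets, .data$mirna, name = "n")
  membership <- tidyr::unnest(select(sets, "pathway", "genes"), "genes") |>
    rename(gene = "genes")
  overlaps <- inner_join(targets, membership, by = "gene",
                         relationship = "many-to-many") |>
    count(.data$mirna, .data$pathway, name = "x")
  grid <- tidyr::expand_grid(mirna = n_by_mirna$mirna, pathway = sets$pathway) |>
    left_join(overlaps, by = c("mirna", "pathway")) |>
    mutate(x = tidyr::replace_na(.data$x, 0L)) |>
    left_join(n_by_mirna, by = "mirna") |>
    left_join(tibble(pathway = sets$pathway, j = lengths(sets$genes)),
              by = "pathway") |>
    mutate(m = m_size)
  if (any(grid$n > m_size)) {
    abort("a target set is larger than the universe; enlarge `m`")
  }
  grid$p_value <- hypergeom_upper(grid$m, grid$j, grid$n, grid$x)
  grid <- if (fdr_scope == "global") {
    mutate(grid, p_adjust = bh_adjust(.data$p_value))
  } else {
    grid |> group_by(.data$mirna) |>
      mutate(p_adjust = bh_adjust(.data$p_value)) |> ungroup()
  }
  grid$significant <- grid$p_adjust < alpha
  grid <- arrange(grid, .data$p_adjust, .data$mirna, .data$pathway)
  if (keep_all) grid else select(filter(grid, .data$significant), -"significant")
}
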