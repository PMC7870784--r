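#' Pairwise pathway crosstalk network
#'
#' Tests every unordered pair of pathways for over-representation of shared
#' genes: for pathways of sizes `j` and `n` in a universe of `m` genes with
#' overlap `x`, the upper-tail hypergeometric probability is computed (the
#' statistic is symmetric in `j` and `n`). P-values are BH-adjusted across
#' all pairs, and pairs with adjusted p below `alpha` become edges of the
#' crosstalk network. Edge weight is `-log10(p_adjust)` (floored at
#' 1e-300), so heavier edges mean stronger association.
#'
#' @param collection Pathway collection tibble; typically restricted to the
#'   significant risk pathways from [enrich_pathways()].
#' @param universe Optional explicit universe (default: union of all genes
#'   in `collection`).
#' @param m Optional fixed universe size.
#' @param alpha Adjusted-p threshold for keeping an edge (default 0.01).
#' @param keep_all If `TRUE`, return all tested pairs with a `significant`
#'   column instead of only the kept edges.
#' @return Tibble of edges with columns `pathway_a`, `pathway_b`
#'   (lexicographically `a < b`), `x`, `j`, `n`, `m`, `p_value`,
#'   `p_adjust`, `weight`.
#' @export
crosstalk_network <- function(collection, universe = NULL, m = NULL,
                              alpha = 0.01, keep_all = FALSE) {
  if (nrow(collection) < 2) abort("need at least 2 pathways for crosstalk")
  sets <- restrict_collection(collection, universe)
  m_size <- if (!is.null(m)) as.integer(m)
  else length(if (is.null(universe)) pathway_universe(collection)
              else unique(toupper(universe)))
  gene_sets <- setNames(sets$genes, sets$pathway)
  ids <- sort(names(gene_sets))
  pairs <- as_tibble(t(utils::combn(ids, 2)), .name_repair = ~ c("pathway_a", "pathway_b"))
  pairs$j <- lengths(gene_sets)[pairs$pathway_a]
  pairs$n <- lengths(gene_sets)[pairs$pathway_b]
  pairs$x <- purrr::map2_int(pairs$pathway_a, pairs$pathway_b, function(a, b) {
    length(intersect(gene_sets[[a]], gene_sets[[b]]))
  })
  if (any(pairs$j > m_size) || any(pairs$n > m_size)) {
    abort("a pathway is larger than the universe; restrict or enlarge `m`")
  }
  pairs$m <- m_size
  pairs$p_value <- hypergeom_upper(pairs$m, pairs$j, pairs$n, pairs$x)
  pairs$p_adjust <- bh_adjust(pairs$p_value)   # family = all pairs
  pairs$weight <- -log10(pmax(pairs$p_adjust, 1e-300))
  pairs$significant <- pairs$p_adjust < alpha
  pairs <- arrange(pairs, .data$p_adjust, .data$pathway_a, .data$pathway_b)
  pairs <- relocate(pairs, "x", .after = "pathway_b")
  if (keep_all) pairs else select(filter(pairs, .data$significant), -"significant")
}

#' Per-pathway crosstalk degree
#'
#' Number of kept crosstalk edges incident to each pathway, sorted by
#' descending degree (ties by pathway id). Pathways can be supplied so that
#' isolated ones appear with degree zero.
#'
#' @param edges Edge tibble from [crosstalk_network()].
#' @param pathways Optional character vector of all pathway ids to report.
#' @return Tibble with columns `pathway`, `degree`.
#' @export
crosstalk_degree <- function(edges, pathways = NULL) {
  ids <- unique(c(edges$pathway_a, edges$pathway_b, pathways))
  deg <- table(factor(c(edges$pathway_a, edges$pathway_b), levels = sort(ids)))
  out <- tibble(pathway = names(deg), degree = as.integer(deg))
  arrange(out, desc(.data$degree), .data$pathway)
}
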