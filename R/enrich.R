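#' Over-representation analysis of a gene list against a pathway collection
#'
#' For each pathway, tests whether the query list shares more genes with it
#' than expected under hypergeometric sampling from the universe, using the
#' upper tail \eqn{P(X \ge x)} (see [hypergeom_upper()]). P-values are
#' BH-adjusted across the full family of pathways in the collection —
#' including pathways with zero overlap, which are part of the tested
#' family even though they are omitted from the returned table.
#'
#' The universe defaults to the union of all genes in the collection. An
#' explicit `universe` restricts both pathways and query to it; query genes
#' outside the universe are dropped (with a warning) and excluded from the
#' query size `n`. Alternatively a fixed integer `m` can stand in for an
#' unenumerated genome-scale universe, in which case no genes are dropped.
#'
#' @param genes Character vector of query gene symbols, or a tibble with a
#'   `gene` column (as from [read_gene_list()]).
#' @param collection Pathway collection tibble (see [read_gmt()]).
#' @param universe Optional explicit universe gene vector.
#' @param m Optional fixed universe size overriding `universe`.
#' @param alpha Adjusted-p significance threshold (default 0.01).
#' @param tail `"upper"` for the over-representation tail (default) or
#'   `"lower"` for the literal lower-tail cumulative sum.
#' @return Tibble with one row per pathway with overlap `x >= 1`: columns
#'   `pathway`, `name`, `category`, `x`, `j`, `n`, `m`, `p_value`,
#'   `p_adjust`, `significant`, and list-column `hits` (the overlapping
#'   genes). Sorted by `p_adjust`, ties broken by pathway id.
#' @export
enrich_pathways <- function(genes, collection, universe = NULL, m = NULL,
                            alpha = 0.01, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  query <- unique(toupper(if (is.data.frame(genes)) genes$gene else genes))
  if (length(query) == 0) abort("query gene list is empty")
  sets <- restrict_collection(collection, universe)
  if (is.null(m)) {
    uni <- if (is.null(universe)) pathway_universe(collection) else unique(toupper(universe))
    m_size <- length(uni)
    kept <- intersect(query, uni)
    if (length(kept) == 0) abort("query outside universe")
    if (length(kept) < length(query)) {
      warn(sprintf("%d query gene(s) absent from the universe were dropped",
                   length(query) - length(kept)))
    }
    query <- kept
  } else {
    if (m < length(query)) abort("`m` smaller than the query size")
    m_size <- as.integer(m)
  }
  n_query <- length(query)
  hits <- lapply(sets$genes, intersect, x = query)
  res <- tibble(
    pathway = sets$pathway, name = sets$name, category = sets$category,
    x = lengths(hits), j = lengths(sets$genes),
    n = n_query, m = m_size, hits = hits
  )
  tail_fun <- if (tail == "upper") hypergeom_upper else hypergeom_lower
  res$p_value <- tail_fun(res$m, res$j, res$n, res$x)
  res$p_adjust <- bh_adjust(res$p_value)   # family = all pathways tested
  res$significant <- res$p_adjust < alpha
  res <- filter(res, .data$x >= 1)
  res <- arrange(res, .data$p_adjust, .data$pathway)
  relocate(res, "hits", .after = "significant")
}

# restrict pathway gene sets to the universe; error if universe excludes an
# entire pathway
restrict_collection <- function(collection, universe) {
  if (is.null(universe)) return(collection)
  universe <- unique(toupper(universe))
  out <- collection
  out$genes <- lapply(collection$genes, intersect, x = universe)
  if (any(lengths(out$genes) == 0)) {
    abort("a pathway has no genes inside the supplied universe")
  }
  out
}

#' Fraction of query genes covered by significant pathways
#'
#' The share of the query list hit by at least one significant pathway —
#' the "how much of the risk-gene list do the enriched pathways explain"
#' summary.
#'
#' @param results Output of [enrich_pathways()].
#' @param genes The query used for enrichment (vector or tibble with `gene`).
#' @return A single fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(results, genes) {
  query <- unique(toupper(if (is.data.frame(genes)) genes$gene else genes))
  sig <- filter(results, .data$significant)
  if (nrow(sig) == 0) return(0)
  covered <- intersect(query, unique(unlist(sig$hits, use.names = FALSE)))
  length(covered) / length(query)
}
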