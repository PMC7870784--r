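#' Run the full miRSNP pathway-network pipeline
#'
#' Chains every stage on a complete input set: risk-gene pathway
#' enrichment, crosstalk among the significant risk pathways, consensus
#' miRNA-target integration, miRNA -> risk-pathway enrichment, miRSNP
#' evidence filtering, PMSN assembly with topology, and axis enumeration.
#'
#' @param inputs A list (e.g. a [generate_bundle()] result or
#'   [read_bundle()] output) with elements `pathways`, `risk_genes`,
#'   `predictions`, `mirsnps`, and optionally `universe`.
#' @param alpha Adjusted-p significance threshold used at every stage.
#' @param k Consensus support threshold for miRNA-target pairs.
#' @param min_dbs Database-consensus threshold for miRSNPs.
#' @param tail Hypergeometric tail (see [enrich_pathways()]).
#' @param crosstalk_scope `"risk-only"` tests pairs among the significant
#'   risk pathways (default); `"vs-all"` tests every pathway pair in the
#'   collection.
#' @param hub_min_degree Strict miRNA-degree threshold for the hub report.
#' @return Object of class `pmsn_run`: list with `enrichment`,
#'   `risk_pathways` (significant collection), `crosstalk`, `consensus`,
#'   `pairs`, `mirsnps` (retained, split by class), `pmsn`, `topology`,
#'   `hubs`, `axes`, and a one-row `summary` tibble of headline counts.
#' @export
run_pipeline <- function(inputs, alpha = 0.01, k = 4, min_dbs = 2,
                         tail = c("upper", "lower"),
                         crosstalk_scope = c("risk-only", "vs-all"),
                         hub_min_degree = 3) {
  tail <- match.arg(tail)
  crosstalk_scope <- match.arg(crosstalk_scope)
  needed <- c("pathways", "risk_genes", "predictions", "mirsnps")
  missing <- setdiff(needed, names(inputs))
  if (length(missing) > 0) {
    abort(paste0("inputs lack element(s): ", paste(missing, collapse = ", ")))
  }
  universe <- inputs$universe

  enrichment <- enrich_pathways(inputs$risk_genes, inputs$pathways,
                                universe = universe, alpha = alpha, tail = tail)
  sig_ids <- enrichment$pathway[enrichment$significant]
  risk_pathways <- filter(inputs$pathways, .data$pathway %in% sig_ids)

  crosstalk <- if (crosstalk_scope == "risk-only") {
    if (nrow(risk_pathways) >= 2) {
      crosstalk_network(risk_pathways, universe = universe, alpha = alpha)
    } else {
      tibble(pathway_a = character(), pathway_b = character())
    }
  } else {
    crosstalk_network(inputs$pathways, universe = universe, alpha = alpha)
  }

  consensus <- build_consensus(inputs$predictions, k = k)
  pairs <- if (nrow(risk_pathways) > 0) {
    mirna_pathway_enrichment(consensus, risk_pathways, universe = universe,
                             alpha = alpha)
  } else {
    tibble(mirna = character(), pathway = character(), p_adjust = numeric())
  }

  retained <- suppressMessages(filter_mirsnps(inputs$mirsnps, min_dbs = min_dbs))
  snps <- split_mirsnps(retained)

  pmsn <- topology <- hubs <- NULL
  if (nrow(pairs) > 0) {
    pmsn <- build_pmsn(pairs, inputs$pathways,
                       target_site_snps = snps$target_site,
                       mirna_gene_snps = snps$mirna_gene)
    topology <- pmsn_topology(pmsn)
    hubs <- hub_report(topology, min_degree = hub_min_degree)
  }
  axes <- extract_axes(snps$target_site, consensus, inputs$risk_genes,
                       pairs, inputs$pathways)

  summary <- tibble(
    n_significant_pathways = length(sig_ids),
    risk_gene_coverage = coverage_fraction(enrichment, inputs$risk_genes),
    n_crosstalk_edges = nrow(crosstalk),
    n_consensus_pairs = nrow(consensus),
    n_mirna_pathway_pairs = nrow(pairs),
    n_network_mirnas = dplyr::n_distinct(pairs$mirna),
    n_network_pathways = dplyr::n_distinct(pairs$pathway),
    n_target_site_snps = nrow(snps$target_site),
    n_mirna_gene_snps = nrow(snps$mirna_gene),
    n_axes = nrow(axes)
  )
  structure(list(enrichment = enrichment, risk_pathways = risk_pathways,
                 crosstalk = crosstalk, consensus = consensus, pairs = pairs,
                 mirsnps = snps, pmsn = pmsn, topology = topology,
                 hubs = hubs, axes = axes, summary = summary,
                 alpha = alpha, k = k, min_dbs = min_dbs),
            class = "pmsn_run")
}

#' @export
print.pmsn_run <- function(x, ...) {
  cat("miRSNP pathway-network pipeline run\n")
  s <- x$summary
  cat(sprintf("  %d significant risk pathways (%.1f%% risk-gene coverage), %d crosstalk edges\n",
              s$n_significant_pathways, 100 * s$risk_gene_coverage,
              s$n_crosstalk_edges))
  cat(sprintf("  %d miRNA-pathway pairs over %d miRNAs and %d pathways\n",
              s$n_mirna_pathway_pairs, s$n_network_mirnas, s$n_network_pathways))
  cat(sprintf("  %d target-site and %d miRNA-gene miRSNPs retained; %d axes\n",
              s$n_target_site_snps, s$n_mirna_gene_snps, s$n_axes))
  invisible(x)
}
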