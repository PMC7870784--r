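#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PMSN into its edge table
#'
#' @param x A [build_pmsn()] result.
#' @param ... Unused.
#' @return Tibble of edges with miRNA, pathway, adjusted p and the number
#'   of annotating target-site miRSNPs.
#' @export
tidy.pmsn <- function(x, ...) {
  as_tibble(x$edges)
}

#' One-row summary of a PMSN
#'
#' @param x A [build_pmsn()] result.
#' @param ... Unused.
#' @return Tibble with node, edge and annotation counts.
#' @export
glance.pmsn <- function(x, ...) {
  tibble(
    n_mirnas = sum(x$nodes$type == "mirna"),
    n_pathways = sum(x$nodes$type == "pathway"),
    n_edges = nrow(x$edges),
    n_edge_snps = nrow(x$edge_snps),
    n_node_snps = nrow(x$node_snps),
    n_unattached_snps = nrow(x$unattached)
  )
}

#' Tidy a topology summary into the per-node table
#'
#' @param x A [pmsn_topology()] result.
#' @param ... Unused.
#' @return Tibble with node, type, degree and normalized betweenness.
#' @export
tidy.pmsn_topology <- function(x, ...) {
  x$nodes
}

#' One-row summary of PMSN topology
#'
#' @param x A [pmsn_topology()] result.
#' @param ... Unused.
#' @return Tibble with node count, edge count and the degree-histogram
#'   power-law fit.
#' @export
glance.pmsn_topology <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = sum(x$nodes$degree) / 2,
    powerlaw_exponent = x$powerlaw$exponent,
    powerlaw_r_squared = x$powerlaw$r_squared
  )
}

#' Tidy a pipeline run into its axis table
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return The flat [axis_report()] table.
#' @export
tidy.pmsn_run <- function(x, ...) {
  axis_report(x$axes)
}

#' One-row summary of a pipeline run
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return The run's headline-count summary tibble.
#' @export
glance.pmsn_run <- function(x, ...) {
  x$summary
}
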