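#' Build the pathway-based miRSNP switching network (PMSN)
#'
#' Assembles the bipartite miRNA-pathway network from the retained
#' significant targeting pairs and decorates it with miRSNP evidence:
#'
#' * a `target_site` SNP record (rsid, miRNA, gene) annotates the edge
#'   (miRNA, pathway) when that edge exists *and* the SNP's gene belongs to
#'   the pathway — the SNP sits in a binding site through which the miRNA
#'   reaches the pathway;
#' * a `mirna_gene` SNP annotates its miRNA's node when that miRNA is in
#'   the network.
#'
#' SNP records that attach nowhere are returned in `$unattached`, never
#' silently dropped.
#'
#' @param pairs Retained pairs from [mirna_pathway_enrichment()] (columns
#'   `mirna`, `pathway`, `p_adjust` used).
#' @param collection Pathway collection covering every pathway in `pairs`
#'   (an unknown pathway id is an error).
#' @param target_site_snps,mirna_gene_snps Filtered miRSNP records (see
#'   [filter_mirsnps()], [split_mirsnps()]); may be `NULL` or empty.
#' @return An object of class `pmsn`: a list with the `igraph` graph
#'   (`$graph`, vertex attribute `type` is `"mirna"`/`"pathway"`), node and
#'   edge tibbles (`$nodes`, `$edges`), SNP annotation tables
#'   (`$edge_snps`, `$node_snps`) and the `$unattached` report.
#' @export
build_pmsn <- function(pairs, collection, target_site_snps = NULL,
                       mirna_gene_snps = NULL) {
  if (nrow(pairs) == 0) abort("no retained miRNA-pathway pairs; nothing to build")
  unknown <- setdiff(unique(pairs$pathway), collection$pathway)
  if (length(unknown) > 0) {
    abort(paste0("pair references unknown pathway id '", unknown[1], "'"))
  }
  edges <- distinct(pairs, .data$mirna, .data$pathway, .keep_all = TRUE)

  empty_snps <- tibble(rsid = character(), mirna = character(), gene = character())
  ts <- if (is.null(target_site_snps) || nrow(target_site_snps) == 0) empty_snps
        else select(target_site_snps, "rsid", "mirna", "gene")
  mg <- if (is.null(mirna_gene_snps) || nrow(mirna_gene_snps) == 0) empty_snps[, c("rsid", "mirna")]
        else select(mirna_gene_snps, "rsid", "mirna")

  membership <- tidyr::unnest(select(collection, "pathway", "genes"), "genes") |>
    rename(gene = "genes")
  edge_snps <- ts |>
    inner_join(select(edges, "mirna", "pathway"), by = "mirna",
               relationship = "many-to-many") |>
    semi_join(membership, by = c("pathway", "gene")) |>
    arrange(.data$rsid, .data$mirna, .data$pathway)
  node_snps <- semi_join(mg, tibble(mirna = unique(edges$mirna)), by = "mirna") |>
    arrange(.data$rsid, .data$mirna)

  unattached <- bind_rows(
    anti_join(ts, distinct(edge_snps, .data$rsid, .data$mirna, .data$gene),
              by = c("rsid", "mirna", "gene")) |> mutate(class = "target_site"),
    anti_join(mg, node_snps, by = c("rsid", "mirna")) |> mutate(class = "mirna_gene")
  )

  edge_counts <- count(edge_snps, .data$mirna, .data$pathway, name = "n_snps")
  edges <- left_join(edges, edge_counts, by = c("mirna", "pathway")) |>
    mutate(n_snps = tidyr::replace_na(.data$n_snps, 0L))
  nodes <- bind_rows(
    tibble(name = sort(unique(edges$mirna)), type = "mirna"),
    tibble(name = sort(unique(edges$pathway)), type = "pathway")
  ) |>
    left_join(count(node_snps, .data$mirna, name = "n_snps"),
              by = c(name = "mirna")) |>
    mutate(n_snps = tidyr::replace_na(.data$n_snps, 0L))

  if (length(intersect(edges$mirna, edges$pathway)) > 0) {
    abort("miRNA and pathway identifiers collide; network would not be bipartite")
  }
  edge_df <- select(edges, from = "mirna", to = "pathway", "p_adjust", "n_snps")
  graph <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                         vertices = nodes)
  structure(list(graph = graph, nodes = nodes, edges = edges,
                 edge_snps = edge_snps, node_snps = node_snps,
                 unattached = unattached),
            class = "pmsn")
}

#' @export
print.pmsn <- function(x, ...) {
  cat("Pathway-based miRSNP switching network\n")
  cat(sprintf("  %d miRNAs, %d pathways, %d edges\n",
              sum(x$nodes$type == "mirna"), sum(x$nodes$type == "pathway"),
              nrow(x$edges)))
  cat(sprintf("  %d target-site SNP edge annotations, %d miRNA-gene SNP node annotations\n",
              nrow(x$edge_snps), nrow(x$node_snps)))
  if (nrow(x$unattached) > 0) {
    cat(sprintf("  %d SNP record(s) could not be attached\n", nrow(x$unattached)))
  }
  invisible(x)
}

#' Topological summary of a PMSN
#'
#' Exact degrees and betweenness centrality (all-pairs shortest-path
#' counting on the bipartite graph as-is, normalized by
#' \eqn{(N-1)(N-2)/2} so values lie in `[0, 1]`), the degree histogram per
#' node class and overall, and a power-law fit of the overall degree
#' histogram (see [fit_powerlaw()]).
#'
#' @param pmsn A [build_pmsn()] result (or a bare `igraph` graph).
#' @return Object of class `pmsn_topology`: list with `$nodes` (node,
#'   type, degree, betweenness), `$histogram` (type, degree, count; type
#'   `"all"` pools both classes) and `$powerlaw` (exponent, slope,
#'   intercept, r_squared).
#' @export
pmsn_topology <- function(pmsn) {
  graph <- if (inherits(pmsn, "pmsn")) pmsn$graph else pmsn
  if (!igraph::is_igraph(graph)) abort("`pmsn` must be a pmsn or igraph object")
  n <- igraph::vcount(graph)
  if (n == 0) abort("graph is empty")
  type <- igraph::vertex_attr(graph, "type") %||% rep("node", n)
  deg <- igraph::degree(graph)
  btw <- if (n <= 2) rep(0, n) else igraph::betweenness(graph, normalized = TRUE)
  nodes <- tibble(node = igraph::V(graph)$name, type = type,
                  degree = as.integer(deg), betweenness = as.numeric(btw)) |>
    arrange(desc(.data$degree), .data$node)
  hist <- bind_rows(
    count(nodes, .data$type, .data$degree, name = "count"),
    count(mutate(nodes, type = "all"), .data$type, .data$degree, name = "count")
  )
  structure(list(
    nodes = nodes, histogram = hist,
    powerlaw = fit_powerlaw(filter(hist, .data$type == "all", .data$degree > 0))
  ), class = "pmsn_topology")
}

#' @export
print.pmsn_topology <- function(x, ...) {
  cat("PMSN topology summary\n")
  cat(sprintf("  %d nodes, sum of degrees %d\n", nrow(x$nodes), sum(x$nodes$degree)))
  if (is.finite(x$powerlaw$exponent)) {
    cat(sprintf("  degree histogram power-law exponent %.3f (R^2 = %.3f)\n",
                x$powerlaw$exponent, x$powerlaw$r_squared))
  }
  invisible(x)
}

#' Fit a power law to a degree histogram
#'
#' Default method is a least-squares line on log10(frequency) versus
#' log10(degree) over non-empty bins, reporting the slope (the exponent is
#' its negation) and the goodness of fit R^2 — the "fitted curve on the
#' histogram" style of scale-free assessment. `method = "mle"` instead
#' returns the continuous-approximation maximum-likelihood exponent
#' \eqn{1 + n / \sum \log(d / (d_{min} - 1/2))} (R^2 is `NA` there).
#'
#' @param degrees Either an integer vector of node degrees, or a histogram
#'   data frame with columns `degree` and `count`.
#' @param method `"ls"` (default) or `"mle"`.
#' @return List with `exponent`, `slope`, `intercept`, `r_squared`.
#' @export
fit_powerlaw <- function(degrees, method = c("ls", "mle")) {
  method <- match.arg(method)
  hist <- if (is.data.frame(degrees)) {
    tibble(degree = degrees$degree, count = degrees$count)
  } else {
    as_tibble(as.data.frame(table(degree = degrees), stringsAsFactors = FALSE)) |>
      mutate(degree = as.integer(.data$degree)) |>
      rename(count = "Freq")
  }
  hist <- filter(hist, .data$degree > 0, .data$count > 0)
  if (method == "mle") {
    d <- rep(hist$degree, hist$count)
    dmin <- min(d)
    exponent <- 1 + length(d) / sum(log(d / (dmin - 0.5)))
    return(list(exponent = exponent, slope = -exponent, intercept = NA_real_,
                r_squared = NA_real_))
  }
  if (nrow(hist) < 2) {
    return(list(exponent = NA_real_, slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_))
  }
  fit <- lm(log10(count) ~ log10(degree), data = hist)
  y <- log10(hist$count)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(exponent = -unname(coef(fit)[2]), slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), r_squared = r2)
}

#' Hub report: highly connected miRNAs and ranked pathways
#'
#' miRNAs interacting with more than `min_degree` pathways, and all pathway
#' nodes ranked by degree then betweenness (ties broken by node id), as a
#' deterministic summary of the network's hubs.
#'
#' @param topology A [pmsn_topology()] result.
#' @param min_degree Strict lower bound on miRNA degree (default 3).
#' @return Named list of tibbles `mirnas` and `pathways`.
#' @export
hub_report <- function(topology, min_degree = 3) {
  nodes <- topology$nodes
  list(
    mirnas = nodes |>
      filter(.data$type == "mirna", .data$degree > min_degree) |>
      arrange(desc(.data$degree), .data$node) |>
      select("node", "degree", "betweenness"),
    pathways = nodes |>
      filter(.data$type == "pathway") |>
      arrange(desc(.data$degree), desc(.data$betweenness), .data$node) |>
      select("node", "degree", "betweenness")
  )
}
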