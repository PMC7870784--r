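#' Enumerate miRSNP -> miRNA -> risk gene -> pathway axes
#'
#' An axis is a SNP in a miRNA binding site of a risk gene, the (possibly
#' family-sized) set of miRNAs sharing that site, and the risk pathways the
#' regulation can reach. Retained target-site SNP records are grouped by
#' (rsid, gene); a group becomes an axis when
#'
#' * the gene is on the risk-gene list,
#' * the gene is a consensus target of *every* miRNA in the group, and
#' * at least one pathway both contains the gene and is significantly
#'   targeted (a retained pair) by at least one miRNA of the group.
#'
#' miRNA family grouping is emergent — miRNAs are grouped because they
#' share the SNP's binding site, not read from an annotation file. A
#' pathway joins the axis when any one axis miRNA links to it.
#'
#' @param target_site_snps Retained `target_site` records (see
#'   [filter_mirsnps()], [split_mirsnps()]).
#' @param consensus Consensus target map from [build_consensus()].
#' @param risk_genes Risk-gene list (vector or tibble with `gene`).
#' @param pairs Retained pairs from [mirna_pathway_enrichment()].
#' @param collection Pathway collection (for gene membership).
#' @return Tibble with one row per axis: `rsid`, `gene`, list-columns
#'   `mirnas` and `pathways`, `n_mirnas`, `n_pathways`, `n_validated`
#'   (axis records with experimental validation), ordered by (rsid, gene).
#'   Zero rows is a valid result.
#' @export
extract_axes <- function(target_site_snps, consensus, risk_genes, pairs,
                         collection) {
  risk <- unique(toupper(if (is.data.frame(risk_genes)) risk_genes$gene else risk_genes))
  empty <- tibble(rsid = character(), gene = character(),
                  mirnas = list(), pathways = list(),
                  n_mirnas = integer(), n_pathways = integer(),
                  n_validated = integer())
  if (is.null(target_site_snps) || nrow(target_site_snps) == 0) return(empty)
  if (!"validated" %in% names(target_site_snps)) target_site_snps$validated <- FALSE

  membership <- tidyr::unnest(select(collection, "pathway", "genes"), "genes") |>
    rename(gene = "genes")
  consensus_pairs <- distinct(consensus, .data$mirna, .data$gene)
  retained_pairs <- distinct(pairs, .data$mirna, .data$pathway)

  groups <- target_site_snps |>
    distinct(.data$rsid, .data$gene, .data$mirna, .data$validated) |>
    group_by(.data$rsid, .data$gene) |>
    summarise(mirnas = list(sort(unique(.data$mirna))),
              n_validated = sum(.data$validated), .groups = "drop") |>
    filter(.data$gene %in% risk)
  if (nrow(groups) == 0) return(empty)

  axes <- purrr::pmap(groups, function(rsid, gene, mirnas, n_validated) {
    # the gene must be a consensus target of every miRNA sharing the site
    supported <- vapply(mirnas, function(mi) {
      any(consensus_pairs$mirna == mi & consensus_pairs$gene == gene)
    }, logical(1))
    if (!all(supported)) return(NULL)
    containing <- membership$pathway[membership$gene == gene]
    linked <- retained_pairs |>
      filter(.data$pathway %in% containing, .data$mirna %in% mirnas)
    paths <- sort(unique(linked$pathway))
    if (length(paths) == 0) return(NULL)
    nm <- length(mirnas)
    tibble(rsid = rsid, gene = gene, mirnas = list(mirnas),
           pathways = list(paths), n_mirnas = nm,
           n_pathways = length(paths), n_validated = n_validated)
  })
  out <- bind_rows(axes)
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$rsid, .data$gene)
}

#' Flat per-pathway axis report
#'
#' One row per (axis, pathway) combination with the miRNA set collapsed to
#' a comma-separated string; stable column order, header-only when no axes
#' exist.
#'
#' @param axes Output of [extract_axes()].
#' @param path Optional TSV output path.
#' @return Tibble with columns `rsid`, `mirnas`, `gene`, `pathway`,
#'   `n_validated` (invisibly when `path` is given).
#' @export
axis_report <- function(axes, path = NULL) {
  out <- if (nrow(axes) == 0) {
    tibble(rsid = character(), mirnas = character(), gene = character(),
           pathway = character(), n_validated = integer())
  } else {
    axes |>
      mutate(mirnas = vapply(.data$mirnas, paste, character(1), collapse = ",")) |>
      tidyr::unnest_longer("pathways", values_to = "pathway") |>
      select("rsid", "mirnas", "gene", "pathway", "n_validated") |>
      arrange(.data$rsid, .data$gene, .data$pathway)
  }
  if (!is.null(path)) {
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
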