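#' Read a GMT gene-set file into a pathway collection
#'
#' GMT is the tab-separated gene-set format: one set per line, first field
#' the set id, second a description, remaining fields the member genes.
#' A description of the form `"name | category"` is split into the `name`
#' and `category` columns; otherwise `category` is `NA`.
#'
#' Gene symbols are uppercased and duplicates within a set collapsed.
#' Malformed lines (fewer than 3 fields) and duplicated pathway ids are
#' errors, not repairs.
#'
#' @param path Path to a GMT file.
#' @return A pathway collection: a tibble with columns `pathway`, `name`,
#'   `category` and the list-column `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("no gene sets in GMT file", class = "mirsnpnet_parse_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields", bad[1]),
          class = "mirsnpnet_parse_error")
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate pathway id '%s'", ids[duplicated(ids)][1]),
          class = "mirsnpnet_parse_error")
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  parts <- strsplit(desc, " | ", fixed = TRUE)
  name <- vapply(parts, `[[`, character(1), 1)
  category <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                     character(1))
  genes <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  if (any(lengths(genes) == 0)) {
    abort("GMT set with no genes", class = "mirsnpnet_parse_error")
  }
  new_pathway_collection(tibble(
    pathway = ids, name = name, category = category, genes = genes
  ))
}

new_pathway_collection <- function(x) {
  class(x) <- c("pathway_collection", class(x))
  x
}

#' Write a pathway collection to a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, f))` reproduces `x` on
#' canonical content (uppercased, deduplicated genes).
#'
#' @param collection A pathway collection tibble (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- ifelse(is.na(collection$category), collection$name,
                 paste(collection$name, collection$category, sep = " | "))
  lines <- mapply(function(id, d, g) paste(c(id, d, g), collapse = "\t"),
                  collection$pathway, desc, collection$genes)
  writeLines(lines, path)
  invisible(path)
}

#' Union of all genes annotated to a pathway collection
#'
#' The default test universe when no explicit universe is supplied.
#'
#' @param collection A pathway collection tibble.
#' @return Character vector of unique gene symbols.
#' @export
pathway_universe <- function(collection) {
  unique(unlist(collection$genes, use.names = FALSE))
}

#' Read a risk-gene list
#'
#' One gene symbol per line; an optional second tab-separated column is kept
#' as free-text evidence annotation. Symbols are uppercased; duplicates are
#' an error.
#'
#' @param path Path to the gene list file.
#' @return Tibble with columns `gene` and `evidence`.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty gene list", class = "mirsnpnet_parse_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  genes <- toupper(vapply(fields, `[[`, character(1), 1))
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene '%s' in gene list", genes[duplicated(genes)][1]),
          class = "mirsnpnet_parse_error")
  }
  evidence <- vapply(fields, function(f) if (length(f) > 1) f[2] else NA_character_,
                     character(1))
  tibble(gene = genes, evidence = evidence)
}

#' Normalize miRNA identifiers
#'
#' Lowercases and ensures the `"hsa-"` species prefix, so `"miR-15b"`,
#' `"hsa-miR-15b"` and `"hsa-mir-15b"` all map to `"hsa-mir-15b"`.
#'
#' @param x Character vector of miRNA names.
#' @return Normalized character vector.
#' @export
normalize_mirna <- function(x) {
  x <- tolower(trimws(x))
  ifelse(startsWith(x, "hsa-"), x, paste0("hsa-", x))
}

#' Read and merge per-source miRNA-target prediction tables
#'
#' Each file is a headerless two-column TSV (`miRNA`, `gene`); the source
#' name is taken from `names(paths)` or, when unnamed, the file name stem.
#' Rows are deduplicated within and across files so each
#' (miRNA, gene, source) triple appears once.
#'
#' @param paths Character vector of file paths, optionally named by source.
#' @param roster Optional declared source roster; a source outside it is an
#'   error.
#' @return Tibble with columns `mirna`, `gene`, `source`.
#' @export
read_predictions <- function(paths, roster = NULL) {
  if (length(paths) == 0) abort("no prediction files given")
  sources <- names(paths)
  if (is.null(sources) || any(!nzchar(sources))) {
    sources <- tools::file_path_sans_ext(basename(paths))
  }
  tabs <- purrr::map2(paths, sources, function(path, source) {
    if (!file.exists(path)) abort(paste0("no such file: ", path))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 2)
    if (length(bad) > 0) {
      abort(sprintf("%s line %d: expected 2 tab-separated fields, found %d",
                    basename(path), bad[1], lengths(fields)[bad[1]]),
            class = "mirsnpnet_parse_error")
    }
    tibble(
      mirna = normalize_mirna(vapply(fields, `[[`, character(1), 1)),
      gene = toupper(vapply(fields, `[[`, character(1), 2)),
      source = source
    )
  })
  out <- distinct(bind_rows(tabs))
  if (!is.null(roster)) {
    unknown <- setdiff(unique(out$source), roster)
    if (length(unknown) > 0) {
      abort(paste0("source '", unknown[1], "' is not in the declared roster"),
            class = "mirsnpnet_parse_error")
    }
  }
  out
}

#' Read a miRSNP evidence table
#'
#' Long-format TSV with header columns `rsid`, `class`, `mirna`, `gene`,
#' `database`, `validated`: one row per (SNP, miRNA, gene, database)
#' support record. `class` is `"target_site"` (SNP in a miRNA binding site;
#' `gene` required) or `"mirna_gene"` (SNP in the miRNA-producing gene;
#' `gene` must be empty). `validated` marks experimental support.
#'
#' @param path Path to the TSV file.
#' @param target_site_roster,mirna_gene_roster Optional declared database
#'   rosters per class; a database outside its roster is an error.
#' @return Tibble with the six columns above (`validated` logical).
#' @export
read_mirsnp_table <- function(path, target_site_roster = NULL,
                              mirna_gene_roster = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("rsid", "class", "mirna", "gene", "database", "validated")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("miRSNP table missing column(s): ", paste(missing, collapse = ", ")),
          class = "mirsnpnet_parse_error")
  }
  tab <- tab[required]
  tab$class <- tolower(tab$class)
  if (!all(tab$class %in% c("target_site", "mirna_gene"))) {
    abort("class must be 'target_site' or 'mirna_gene'", class = "mirsnpnet_parse_error")
  }
  if (!all(grepl("^rs[0-9]+$", tab$rsid))) {
    abort("rsid must match rs[0-9]+", class = "mirsnpnet_parse_error")
  }
  tab$mirna <- normalize_mirna(tab$mirna)
  tab$gene <- toupper(ifelse(is.na(tab$gene), "", tab$gene))
  if (any(tab$class == "target_site" & !nzchar(tab$gene))) {
    abort("target_site records must carry a gene symbol", class = "mirsnpnet_parse_error")
  }
  if (any(tab$class == "mirna_gene" & nzchar(tab$gene))) {
    abort("mirna_gene records must not carry a gene symbol", class = "mirsnpnet_parse_error")
  }
  tab$gene <- ifelse(nzchar(tab$gene), tab$gene, NA_character_)
  tab$validated <- toupper(tab$validated) %in% c("TRUE", "T", "1", "YES")
  for (cls in c("target_site", "mirna_gene")) {
    roster <- if (cls == "target_site") target_site_roster else mirna_gene_roster
    if (!is.null(roster)) {
      unknown <- setdiff(unique(tab$database[tab$class == cls]), roster)
      if (length(unknown) > 0) {
        abort(paste0("database '", unknown[1], "' not in the ", cls, " roster"),
              class = "mirsnpnet_parse_error")
      }
    }
  }
  as_tibble(tab)
}

#' Serialize a network to GraphML or an edge-list TSV
#'
#' @param graph An `igraph` object or a [build_pmsn()] result.
#' @param path Output path.
#' @param format `"graphml"` or `"tsv"` (tab-separated edge list with
#'   attributes).
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (inherits(graph, "pmsn")) graph <- graph$graph
  if (!igraph::is_igraph(graph)) abort("`graph` must be an igraph or pmsn object")
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    edges <- igraph::as_data_frame(graph, what = "edges")
    readr::write_tsv(tibble::as_tibble(edges), path, progress = FALSE)
  }
  invisible(path)
}

#' Packaged KEGG enrichment table of the 54 post-stroke depression risk genes
#'
#' The published over-representation result for the curated risk-gene list:
#' 22 KEGG pathways with their BH-adjusted p-values and category labels,
#' shipped as a plain-text fixture. All printed rows fall below the 0.01
#' adjusted-p significance threshold used throughout the pipeline.
#'
#' @return Tibble with columns `pathway`, `name`, `p_adjust`, `category`,
#'   ordered by adjusted p.
#' @export
load_psd_enrichment_fixture <- function() {
  path <- system.file("extdata", "psd_kegg_enrichment.tsv",
                      package = "mirsnpnet", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccdc", progress = FALSE)
}

#' Packaged worked-example fixture: the rs28457673 / IGF1R axis
#'
#' A small, hand-constructed input bundle reproducing the published worked
#' example in which the 3'-UTR SNP rs28457673 sits in the IGF1R binding
#' sites of five miR-15/16/195/497-family miRNAs, and IGF1R belongs to the
#' MAPK (hsa04010), PI3K-Akt (hsa04151) and EGFR-TKI-resistance (hsa01521)
#' pathways. Running [filter_mirsnps()], [build_consensus()] and
#' [extract_axes()] on it yields that single axis.
#'
#' @return List with elements `mirsnps`, `predictions`, `pathways`,
#'   `risk_genes` and `pairs` (retained miRNA-pathway pairs).
#' @export
load_axis_example_fixture <- function() {
  dir <- system.file("extdata", package = "mirsnpnet", mustWork = TRUE)
  pred_path <- file.path(dir, "axis_example_predictions.tsv")
  pred <- readr::read_tsv(pred_path, col_types = "ccc", progress = FALSE)
  list(
    mirsnps = read_mirsnp_table(file.path(dir, "axis_example_mirsnps.tsv")),
    predictions = pred,
    pathways = read_gmt(file.path(dir, "axis_example_pathways.gmt")),
    risk_genes = read_gene_list(file.path(dir, "axis_example_risk_genes.tsv")),
    pairs = readr::read_tsv(file.path(dir, "axis_example_pairs.tsv"),
                            col_types = "cciiiidd", progress = FALSE)
  )
}
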