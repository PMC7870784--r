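#' Collapse a long miRSNP table into per-record evidence
#'
#' One record per (rsid, class, mirna, gene) with its set of distinct
#' supporting databases and an any-database experimental-validation flag.
#' A SNP shared by several miRNAs (a family binding site) yields one record
#' per (rsid, mirna, gene) triple.
#'
#' @param snps Long-format tibble as from [read_mirsnp_table()].
#' @return Tibble with columns `rsid`, `class`, `mirna`, `gene`,
#'   `databases` (list-column), `n_dbs`, `validated`.
#' @export
collapse_mirsnps <- function(snps) {
  snps |>
    group_by(.data$rsid, .data$class, .data$mirna, .data$gene) |>
    summarise(databases = list(sort(unique(.data$database))),
              n_dbs = dplyr::n_distinct(.data$database),
              validated = any(.data$validated), .groups = "drop") |>
    arrange(.data$rsid, .data$mirna, .data$gene)
}

#' Filter miRSNP records by evidence strength
#'
#' A record is retained when it is experimentally validated *or* supported
#' by at least `min_dbs` distinct databases (the two clauses are a
#' disjunction: validation alone suffices). Retention counts per class are
#' reported as a message.
#'
#' @param records Collapsed records from [collapse_mirsnps()], or a long
#'   table from [read_mirsnp_table()] (collapsed automatically).
#' @param min_dbs Minimum distinct supporting databases (default 2).
#' @return The retained records, same shape as [collapse_mirsnps()] output.
#' @export
filter_mirsnps <- function(records, min_dbs = 2) {
  if (min_dbs < 1) abort("`min_dbs` must be at least 1")
  if (!"n_dbs" %in% names(records)) records <- collapse_mirsnps(records)
  kept <- filter(records, .data$validated | .data$n_dbs >= min_dbs)
  counts <- count(kept, .data$class)
  inform(paste0("retained ", nrow(kept), "/", nrow(records), " miRSNP records (",
                paste(counts$class, counts$n, sep = ": ", collapse = ", "), ")"))
  kept
}

#' Partition miRSNP records by class
#'
#' @param records Collapsed (and usually filtered) miRSNP records.
#' @return Named list with tibbles `target_site` (SNPs in miRNA binding
#'   sites) and `mirna_gene` (SNPs in miRNA-producing genes).
#' @export
split_mirsnps <- function(records) {
  if (!"class" %in% names(records)) abort("records lack a `class` column")
  list(
    target_site = filter(records, .data$class == "target_site"),
    mirna_gene = filter(records, .data$class == "mirna_gene")
  )
}
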