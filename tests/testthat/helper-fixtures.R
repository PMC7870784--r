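# Shared in-code fixtures for the unit tests.

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

make_collection <- function(sets, categories = NULL) {
  mirsnpnet:::new_pathway_collection(tibble::tibble(
    pathway = names(sets),
    name = paste("set", names(sets)),
    category = categories %||% rep(NA_character_, length(sets)),
    genes = lapply(unname(sets), toupper)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a reduced-scale generator configuration that keeps unit tests fast while
# preserving every planted structure class
small_config <- function(seed, ...) {
  synth_config(seed = seed, m = 4000, n_pathways = 60,
               pathway_size_range = c(15, 80), n_mirnas = 80,
               n_planted_mirnas = 12, target_range = c(15, 60),
               n_target_site_snps = 20, n_mirna_gene_snps = 6, ...)
}

mirsnp_records <- function(...) {
  rows <- list(...)
  tibble::tibble(
    rsid = vapply(rows, `[[`, character(1), 1),
    class = vapply(rows, `[[`, character(1), 2),
    mirna = vapply(rows, `[[`, character(1), 3),
    gene = vapply(rows, function(r) if (is.na(r[[4]])) NA_character_ else r[[4]], character(1)),
    database = vapply(rows, `[[`, character(1), 5),
    validated = vapply(rows, function(r) as.logical(r[[6]]), logical(1))
  )
}
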