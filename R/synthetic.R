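#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: a gene universe, a
#' pathway collection with planted crosstalk blocks, a risk-gene list
#' enriched in designated pathways, per-tool miRNA-target prediction tables
#' with tunable inter-source agreement, and multi-database miRSNP tables.
#' Defaults mirror the scale of the real analysis: 54 risk genes, 10
#' prediction tools, a 4-database target-site roster and a 3-database
#' miRNA-gene roster, a 20,000-gene universe with 300 pathways, and 42 + 12
#' planted miRSNPs of the two classes.
#'
#' Inter-source agreement is modeled as independent per-source Bernoulli
#' detection of true pairs (probability `sensitivity`) plus uniform false
#' positives (`fp_rate` of all miRNA x gene combinations per source).
#' miRNAs without a planted pathway link draw their targets outside the
#' planted pathways, so the no-link ground truth is unambiguous and
#' consistent with the emitted files by construction.
#'
#' @param seed Mandatory RNG seed.
#' @param m Universe size.
#' @param n_pathways Number of pathways; sizes log-uniform on
#'   `pathway_size_range`.
#' @param pathway_size_range Length-2 range of pathway sizes.
#' @param n_risk_genes Size of the risk-gene list.
#' @param n_planted_pathways Number of pathways (`c`) the risk list is
#'   planted into.
#' @param enrichment_strength Fraction of risk genes drawn from planted
#'   pathways.
#' @param crosstalk_shared Shared-gene block size between consecutive
#'   planted pathways (the planted crosstalk edges).
#' @param n_mirnas Number of miRNAs.
#' @param target_range Log-uniform range of per-miRNA true-target counts.
#' @param n_sources Prediction-tool roster size.
#' @param sensitivity Per-source detection probability of a true pair.
#' @param fp_rate Per-source false-positive rate over all miRNA x gene
#'   combinations.
#' @param consensus_k Consensus threshold the planted structure must
#'   survive.
#' @param n_planted_mirnas Number of miRNAs with planted pathway targeting.
#' @param targeting_fraction Fraction of a planted pathway's genes included
#'   in a planted miRNA's true target set.
#' @param n_target_site_snps,n_mirna_gene_snps Planted (filter-surviving)
#'   miRSNP counts per class.
#' @param n_noise_snps miRSNP records designed to fail the evidence filter.
#' @param target_site_dbs,mirna_gene_dbs Database rosters per class.
#' @param min_dbs Database-consensus threshold planted SNPs must survive.
#' @param validated_fraction Fraction of planted SNPs flagged as
#'   experimentally validated.
#' @param axes List of planted axis specs; see [plant_axis()].
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         m = 20000,
                         n_pathways = 300,
                         pathway_size_range = c(20, 300),
                         n_risk_genes = 54,
                         n_planted_pathways = 5,
                         enrichment_strength = 0.6,
                         crosstalk_shared = 10,
                         n_mirnas = 500,
                         target_range = c(20, 200),
                         n_sources = 10,
                         sensitivity = 0.7,
                         fp_rate = 0.001,
                         consensus_k = 4,
                         n_planted_mirnas = 30,
                         targeting_fraction = 0.5,
                         n_target_site_snps = 42,
                         n_mirna_gene_snps = 12,
                         n_noise_snps = 20,
                         target_site_dbs = c("polymirts", "mirnasnp", "mirsnp", "msdd"),
                         mirna_gene_dbs = c("mirnasnp", "polymirts", "msdd"),
                         min_dbs = 2,
                         validated_fraction = 0.2,
                         axes = list()) {
  if (missing(seed)) abort("`seed` is mandatory")
  cfg <- as.list(environment())
  for (p in c("enrichment_strength", "sensitivity", "fp_rate",
              "targeting_fraction", "validated_fraction")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(paste0("`", p, "` must be a probability in [0, 1]"))
    }
  }
  for (p in c("m", "n_pathways", "n_risk_genes", "n_planted_pathways",
              "n_mirnas", "n_sources", "n_planted_mirnas")) {
    if (cfg[[p]] < 1) abort(paste0("`", p, "` must be positive"))
  }
  if (n_risk_genes > m) abort("risk-gene count exceeds the universe size")
  if (n_planted_pathways > n_pathways) {
    abort("more planted pathways than pathways")
  }
  if (consensus_k > n_sources) abort("`consensus_k` exceeds the source roster")
  if (min_dbs > length(target_site_dbs)) {
    abort("`min_dbs` exceeds the target-site database roster")
  }
  if (max(pathway_size_range) * n_planted_pathways + crosstalk_shared > m) {
    abort("planted pathways cannot fit disjointly in the universe")
  }
  if (n_planted_mirnas > n_mirnas) abort("more planted miRNAs than miRNAs")
  structure(cfg, class = "synth_config")
}

#' Plant a miRSNP -> miRNA -> gene -> pathway axis into a configuration
#'
#' Adds an axis specification the generator is guaranteed to realize so
#' that it survives every downstream filter: a dedicated risk gene placed
#' in `n_pathways` planted pathways, `n_mirnas` dedicated miRNAs that all
#' target the gene with forced `>= consensus_k` source support and strongly
#' target the chosen pathways (so the miRNA-pathway pairs are retained),
#' and a shared validated target-site SNP on the gene with at least
#' `min_dbs` supporting databases.
#'
#' @param config A [synth_config()] object.
#' @param n_mirnas Number of miRNAs sharing the SNP's binding site.
#' @param n_pathways Number of planted pathways the axis reaches (must be
#'   between 1 and `n_planted_pathways`).
#' @param gene Optional fixed gene symbol for the axis.
#' @return The configuration with the axis appended.
#' @export
plant_axis <- function(config, n_mirnas, n_pathways, gene = NULL) {
  if (!inherits(config, "synth_config")) abort("`config` must be a synth_config")
  if (n_mirnas < 1) abort("an axis needs at least one miRNA")
  if (n_pathways < 1) abort("an axis needs at least one pathway")
  if (n_pathways > config$n_planted_pathways) {
    abort("axis spans more pathways than are planted")
  }
  config$axes <- c(config$axes,
                   list(list(n_mirnas = n_mirnas, n_pathways = n_pathways,
                             gene = if (!is.null(gene)) toupper(gene) else NULL)))
  config
}

#' Generate a synthetic input bundle with planted structure
#'
#' Produces every pipeline input in memory, plus a ground-truth table that
#' is consistent with the emitted data by construction. The same seed and
#' configuration always yield an identical bundle.
#'
#' Planted structure: `n_planted_pathways` pairwise-disjoint pathways
#' except for `crosstalk_shared`-gene blocks between consecutive ones (the
#' planted crosstalk chain); risk genes distributed evenly across the
#' planted pathways' exclusive genes; `n_planted_mirnas` miRNAs each
#' targeting `targeting_fraction` of one to `n_planted_pathways` planted
#' pathways (the planted miRNA-pathway pairs); filter-surviving miRSNPs of
#' both classes attached to that structure (target-site SNPs are drawn on
#' non-risk target genes so planted axes remain the only axis ground
#' truth); and any axes added with [plant_axis()].
#'
#' @param config A [synth_config()] object.
#' @return A list of class `synth_bundle` with elements `universe`,
#'   `pathways` (collection tibble), `risk_genes`, `predictions`,
#'   `mirsnps` (long format), `config`, and `truth` (planted pathways,
#'   crosstalk edges, true targets, planted pairs, per-class miRSNP
#'   counts, planted axes, per-pathway planted risk-gene hits).
#' @export
generate_bundle <- function(config) {
  if (!inherits(config, "synth_config")) abort("`config` must be a synth_config")
  set.seed(config$seed)
  cfg <- config
  genes <- sprintf("G%05d", seq_len(cfg$m))

  ## --- pathways ------------------------------------------------------
  sizes <- pmin(cfg$m, round(exp(stats::runif(
    cfg$n_pathways, log(cfg$pathway_size_range[1]), log(cfg$pathway_size_range[2])))))
  ids <- sprintf("PW%04d", seq_len(cfg$n_pathways))
  planted_ids <- ids[seq_len(cfg$n_planted_pathways)]

  # planted pathways: disjoint gene segments + shared blocks between
  # consecutive pathways so crosstalk has exact planted adjacency
  pool <- sample(genes, sum(sizes[seq_len(cfg$n_planted_pathways)]))
  sets <- vector("list", cfg$n_pathways)
  offset <- 0
  for (i in seq_len(cfg$n_planted_pathways)) {
    seg <- pool[(offset + 1):(offset + sizes[i])]
    offset <- offset + sizes[i]
    if (i > 1) {
      # the shared block is capped at a quarter of the smaller neighbor so
      # every planted pathway keeps enough exclusive genes for its planted
      # risk-gene and miRNA-targeting signal to be realizable
      block <- max(1, min(cfg$crosstalk_shared,
                          floor(min(sizes[i], sizes[i - 1]) / 4)))
      shared <- sample(setdiff(sets[[i - 1]], unlist(sets[seq_len(i - 2)])),
                       block)
      seg <- c(shared, seg[seq_len(sizes[i] - length(shared))])
    }
    sets[[i]] <- seg
  }
  planted_union <- unique(unlist(sets[seq_len(cfg$n_planted_pathways)]))
  if (cfg$n_pathways > cfg$n_planted_pathways) {
    for (i in (cfg$n_planted_pathways + 1):cfg$n_pathways) {
      sets[[i]] <- sample(genes, sizes[i])
    }
  }

  ## --- planted axes: dedicated genes placed into planted pathways -----
  decoy_pool <- setdiff(genes, planted_union)
  axis_defs <- list()
  if (length(cfg$axes) > 0) {
    for (a in seq_along(cfg$axes)) {
      spec <- cfg$axes[[a]]
      ax_gene <- spec$gene %||% sample(decoy_pool, 1)
      decoy_pool <- setdiff(decoy_pool, ax_gene)
      ax_paths <- sort(sample(planted_ids, spec$n_pathways))
      for (pid in ax_paths) {
        idx <- match(pid, ids)
        sets[[idx]] <- unique(c(sets[[idx]], ax_gene))
      }
      axis_defs[[a]] <- list(gene = ax_gene, pathways = ax_paths,
                             n_mirnas = spec$n_mirnas,
                             mirnas = sprintf("hsa-mir-a%d-%d", a,
                                              seq_len(spec$n_mirnas)),
                             rsid = sprintf("rs9900%03d", a))
    }
    planted_union <- unique(c(planted_union,
                              vapply(axis_defs, `[[`, character(1), "gene")))
  }
  collection <- new_pathway_collection(tibble(
    pathway = ids, name = paste("synthetic pathway", ids),
    category = NA_character_, genes = sets
  ))

  ## --- risk genes ----------------------------------------------------
  n_enriched <- round(cfg$enrichment_strength * cfg$n_risk_genes)
  # spread enriched risk genes evenly over the planted pathways' exclusive
  # genes so every planted pathway receives a strong overlap
  per_path <- diff(round(seq(0, n_enriched, length.out = cfg$n_planted_pathways + 1)))
  planted_hits <- purrr::map2(seq_len(cfg$n_planted_pathways), per_path, function(i, np) {
    exclusive <- setdiff(sets[[i]], unlist(sets[seq_len(cfg$n_planted_pathways)[-i]]))
    sample(exclusive, min(np, length(exclusive)))
  })
  risk_enriched <- unique(unlist(planted_hits))
  risk_rest <- sample(setdiff(genes, c(planted_union, risk_enriched)),
                      cfg$n_risk_genes - length(risk_enriched))
  axis_genes <- vapply(axis_defs, `[[`, character(1), "gene")
  risk_genes <- tibble(gene = c(risk_enriched, axis_genes, risk_rest),
                       evidence = NA_character_)

  ## --- miRNAs and true targets ---------------------------------------
  mirnas <- sprintf("hsa-mir-%04d", seq_len(cfg$n_mirnas))
  planted_mirnas <- sort(sample(mirnas, cfg$n_planted_mirnas))
  target_counts <- round(exp(stats::runif(
    cfg$n_mirnas, log(cfg$target_range[1]), log(cfg$target_range[2]))))
  names(target_counts) <- mirnas

  planted_pairs <- list()
  true_targets <- vector("list", cfg$n_mirnas)
  names(true_targets) <- mirnas
  path_sets <- setNames(sets, ids)
  # planted targeting is sampled from each pathway's exclusive genes (not
  # the shared crosstalk blocks or axis genes), so a planted miRNA overlaps
  # exactly its assigned pathways and the no-link ground truth is exact
  axis_genes_all <- vapply(axis_defs, `[[`, character(1), "gene")
  exclusive_sets <- setNames(lapply(seq_len(cfg$n_planted_pathways), function(i) {
    setdiff(sets[[i]], c(unlist(sets[seq_len(cfg$n_planted_pathways)[-i]]),
                         axis_genes_all))
  }), planted_ids)
  for (mi in mirnas) {
    if (mi %in% planted_mirnas) {
      d <- sample.int(cfg$n_planted_pathways, 1)
      tgt_paths <- sort(sample(planted_ids, d))
      planted_part <- unique(unlist(lapply(tgt_paths, function(pid) {
        pg <- exclusive_sets[[pid]]
        sample(pg, ceiling(cfg$targeting_fraction * length(pg)))
      })))
      extra <- max(0, target_counts[[mi]] - length(planted_part))
      true_targets[[mi]] <- c(planted_part, sample(decoy_pool, extra))
      planted_pairs[[mi]] <- tibble(mirna = mi, pathway = tgt_paths)
    } else {
      true_targets[[mi]] <- sample(decoy_pool, target_counts[[mi]])
    }
  }
  planted_pairs <- bind_rows(planted_pairs)

  ## --- axis miRNAs: forced-consensus targeting ------------------------
  forced <- list()
  for (a in seq_along(axis_defs)) {
    def <- axis_defs[[a]]
    for (mi in def$mirnas) {
      planted_part <- unique(c(def$gene, unlist(lapply(def$pathways, function(pid) {
        pg <- exclusive_sets[[pid]]
        sample(pg, ceiling(cfg$targeting_fraction * length(pg)))
      }))))
      true_targets[[mi]] <- planted_part
      planted_pairs <- bind_rows(planted_pairs,
                                 tibble(mirna = mi, pathway = def$pathways))
      forced[[length(forced) + 1]] <- tibble(mirna = mi, gene = planted_part)
    }
  }
  true_tab <- bind_rows(purrr::imap(true_targets, function(g, mi) {
    tibble(mirna = mi, gene = g)
  }))
  forced_tab <- bind_rows(forced)

  ## --- per-source prediction tables -----------------------------------
  sources <- sprintf("tool%02d", seq_len(cfg$n_sources))
  n_true <- nrow(true_tab)
  support <- matrix(stats::runif(n_true * cfg$n_sources) < cfg$sensitivity,
                    nrow = n_true)
  if (nrow(forced_tab) > 0) {
    # axis pairs must clear the >= k-of-N consensus deterministically
    fidx <- which(paste(true_tab$mirna, true_tab$gene) %in%
                    paste(forced_tab$mirna, forced_tab$gene))
    for (r in fidx) {
      short <- cfg$consensus_k - sum(support[r, ])
      if (short > 0) {
        support[r, sample(which(!support[r, ]), short)] <- TRUE
      }
    }
  }
  pred <- purrr::map(seq_len(cfg$n_sources), function(s) {
    hit <- true_tab[support[, s], ]
    n_fp <- stats::rpois(1, cfg$fp_rate * cfg$n_mirnas * cfg$m)
    fp <- tibble(mirna = sample(mirnas, n_fp, replace = TRUE),
                 gene = sample(genes, n_fp, replace = TRUE))
    mutate(distinct(bind_rows(hit, fp)), source = sources[s])
  })
  predictions <- bind_rows(pred)

  ## --- miRSNPs --------------------------------------------------------
  edge_cand <- planted_pairs |>
    filter(!.data$mirna %in% unlist(lapply(axis_defs, `[[`, "mirnas"))) |>
    purrr::pmap(function(mirna, pathway) {
      g <- setdiff(intersect(true_targets[[mirna]], path_sets[[pathway]]),
                   risk_genes$gene)
      if (length(g) == 0) return(NULL)
      tibble(mirna = mirna, gene = g)
    }) |>
    bind_rows() |>
    distinct()
  if (nrow(edge_cand) < cfg$n_target_site_snps) {
    abort("not enough planted edge-supporting (miRNA, gene) pairs for the requested target-site miRSNPs")
  }
  ts_rows <- edge_cand[sample.int(nrow(edge_cand), cfg$n_target_site_snps), ]
  ts_snps <- make_snps(ts_rows, class = "target_site",
                       rs_start = 1e6, roster = cfg$target_site_dbs,
                       min_dbs = cfg$min_dbs,
                       validated_fraction = cfg$validated_fraction)
  mg_rows <- tibble(mirna = sample(unique(planted_pairs$mirna),
                                   cfg$n_mirna_gene_snps, replace = FALSE),
                    gene = NA_character_)
  mg_snps <- make_snps(mg_rows, class = "mirna_gene",
                       rs_start = 2e6, roster = cfg$mirna_gene_dbs,
                       min_dbs = min(cfg$min_dbs, length(cfg$mirna_gene_dbs)),
                       validated_fraction = cfg$validated_fraction)
  noise <- if (cfg$n_noise_snps > 0) {
    tibble(
      rsid = sprintf("rs%07d", 3e6 + seq_len(cfg$n_noise_snps)),
      class = sample(c("target_site", "mirna_gene"), cfg$n_noise_snps, replace = TRUE),
      mirna = sample(mirnas, cfg$n_noise_snps, replace = TRUE),
      database = NA_character_, validated = FALSE
    ) |>
      mutate(gene = ifelse(.data$class == "target_site",
                           sample(genes, cfg$n_noise_snps, replace = TRUE),
                           NA_character_),
             database = ifelse(.data$class == "target_site",
                               sample(cfg$target_site_dbs, cfg$n_noise_snps, replace = TRUE),
                               sample(cfg$mirna_gene_dbs, cfg$n_noise_snps, replace = TRUE))) |>
      select("rsid", "class", "mirna", "gene", "database", "validated")
  } else NULL
  axis_snps <- bind_rows(purrr::map(axis_defs, function(def) {
    tidyr::expand_grid(mirna = def$mirnas,
                       database = sample(cfg$target_site_dbs,
                                         max(cfg$min_dbs, 2))) |>
      mutate(rsid = def$rsid, class = "target_site", gene = def$gene,
             validated = TRUE) |>
      select("rsid", "class", "mirna", "gene", "database", "validated")
  }))
  mirsnps <- bind_rows(ts_snps, mg_snps, axis_snps, noise)

  truth <- list(
    planted_pathways = planted_ids,
    planted_crosstalk = if (cfg$n_planted_pathways > 1) {
      tibble(pathway_a = planted_ids[-cfg$n_planted_pathways],
             pathway_b = planted_ids[-1])
    } else tibble(pathway_a = character(), pathway_b = character()),
    planted_risk_hits = setNames(lapply(planted_hits, sort), planted_ids),
    true_targets = true_tab,
    planted_pairs = arrange(planted_pairs, .data$mirna, .data$pathway),
    planted_mirnas = planted_mirnas,
    mirsnp_counts = c(target_site = cfg$n_target_site_snps +
                        sum(vapply(axis_defs, function(d) length(d$mirnas), integer(1))),
                      mirna_gene = cfg$n_mirna_gene_snps),
    planted_axes = if (length(axis_defs) > 0) {
      tibble(rsid = vapply(axis_defs, `[[`, character(1), "rsid"),
             gene = vapply(axis_defs, `[[`, character(1), "gene"),
             mirnas = lapply(axis_defs, function(d) sort(d$mirnas)),
             pathways = lapply(axis_defs, `[[`, "pathways"))
    } else tibble(rsid = character(), gene = character(),
                  mirnas = list(), pathways = list())
  )
  structure(list(universe = genes, pathways = collection,
                 risk_genes = risk_genes, predictions = predictions,
                 mirsnps = mirsnps, truth = truth, config = cfg),
            class = "synth_bundle")
}

# long-format miRSNP rows for planted records: always >= min_dbs databases
make_snps <- function(rows, class, rs_start, roster, min_dbs, validated_fraction) {
  if (nrow(rows) == 0) return(NULL)
  purrr::pmap(cbind(rows, i = seq_len(nrow(rows))), function(mirna, gene, i) {
    choices <- seq(min_dbs, length(roster))
    n_dbs <- choices[sample.int(length(choices), 1)]
    tibble(rsid = sprintf("rs%07d", rs_start + i), class = class,
           mirna = mirna, gene = gene,
           database = sample(roster, n_dbs),
           validated = stats::runif(1) < validated_fraction)
  }) |> bind_rows()
}

#' Write a synthetic bundle to disk
#'
#' Emits the same plain-text formats the readers consume — `pathways.gmt`,
#' `risk_genes.tsv`, `universe.txt`, one headerless two-column TSV per
#' prediction source under `predictions/`, `mirsnps.tsv` — plus
#' `truth.json` with the planted ground truth.
#'
#' @param bundle A [generate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "predictions"), recursive = TRUE, showWarnings = FALSE)
  write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  writeLines(bundle$risk_genes$gene, file.path(dir, "risk_genes.tsv"))
  writeLines(bundle$universe, file.path(dir, "universe.txt"))
  for (s in sort(unique(bundle$predictions$source))) {
    sub <- filter(bundle$predictions, .data$source == s)
    writeLines(paste(sub$mirna, sub$gene, sep = "\t"),
               file.path(dir, "predictions", paste0(s, ".tsv")))
  }
  readr::write_tsv(bundle$mirsnps, file.path(dir, "mirsnps.tsv"), progress = FALSE)
  truth <- bundle$truth
  truth$planted_risk_hits <- lapply(truth$planted_risk_hits, identity)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a written synthetic bundle back through the standard readers
#'
#' @param dir Directory written by [write_bundle()].
#' @return List with `pathways`, `risk_genes`, `universe`, `predictions`,
#'   `mirsnps`.
#' @export
read_bundle <- function(dir) {
  pred_files <- sort(list.files(file.path(dir, "predictions"), full.names = TRUE))
  list(
    pathways = read_gmt(file.path(dir, "pathways.gmt")),
    risk_genes = read_gene_list(file.path(dir, "risk_genes.tsv")),
    universe = readLines(file.path(dir, "universe.txt")),
    predictions = read_predictions(pred_files),
    mirsnps = read_mirsnp_table(file.path(dir, "mirsnps.tsv"))
  )
}
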