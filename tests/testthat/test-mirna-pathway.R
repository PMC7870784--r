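pred_row <- function(mirna, gene, sources) {
  tibble::tibble(mirna = mirna, gene = gene, source = sources)
}

test_that("consensus keeps pairs with >= k distinct sources and drops the rest", {
  pred <- dplyr::bind_rows(
    pred_row("miR-a", "g1", paste0("tool", 1:4)),   # 4 of 10 -> kept
    pred_row("miR-b", "g2", paste0("tool", 1:3)),   # 3 -> dropped
    pred_row("miR-c", "g3", c("tool1", "tool1"))    # same source twice -> support 1
  )
  cons <- build_consensus(pred, k = 4, n_sources = 10)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$mirna, "hsa-mir-a")
  expect_equal(cons$n_sources, 4L)
  cons2 <- build_consensus(pred, k = 2, n_sources = 10)
  expect_false("hsa-mir-c" %in% cons2$mirna)
  expect_error(build_consensus(pred[0, ], k = 4), "empty")
  expect_error(build_consensus(pred, k = 11, n_sources = 10), "between 1")
})

test_that("raising k never enlarges target sets, and input order is irrelevant", {
  b <- generate_bundle(small_config(seed = 21))
  for_k <- lapply(c(2, 4, 6), function(k) build_consensus(b$predictions, k = k))
  for (i in 2:3) {
    prev <- paste(for_k[[i - 1]]$mirna, for_k[[i - 1]]$gene)
    cur <- paste(for_k[[i]]$mirna, for_k[[i]]$gene)
    expect_true(all(cur %in% prev))
  }
  shuffled <- b$predictions[sample.int(nrow(b$predictions)), ]
  expect_equal(build_consensus(shuffled, k = 4), build_consensus(b$predictions, k = 4),
               ignore_attr = TRUE)
})

test_that("a miRNA whose targets equal a pathway's gene set attains minimal p", {
  col <- make_collection(list(p1 = paste0("G", 1:10), p2 = paste0("G", 51:70)))
  cons <- tibble::tibble(mirna = c(rep("hsa-mir-z", 10), rep("hsa-mir-w", 5)),
                         gene = c(paste0("G", 1:10), paste0("G", 96:100)),
                         n_sources = 5L)
  pairs <- mirna_pathway_enrichment(cons, col, universe = paste0("G", 1:2000),
                                    alpha = 0.01)
  expect_equal(pairs$mirna[1], "hsa-mir-z")
  expect_equal(pairs$pathway[1], "p1")
  expect_equal(pairs$x[1], 10L)
  # miRNAs with no retained pair are absent from the output
  expect_false("hsa-mir-w" %in% pairs$mirna)
})

test_that("pair p-values match the enumeration oracle on a 20-gene universe", {
  universe <- paste0("G", 1:20)
  col <- make_collection(list(a = paste0("G", 1:6), b = paste0("G", 5:12)))
  cons <- tibble::tibble(mirna = c(rep("hsa-mir-1", 5), rep("hsa-mir-2", 7)),
                         gene = c(paste0("G", c(1, 3, 5, 9, 15)),
                                  paste0("G", c(2, 6, 7, 8, 11, 17, 19))),
                         n_sources = 4L)
  all_tests <- mirna_pathway_enrichment(cons, col, universe = universe,
                                        keep_all = TRUE)
  expect_equal(nrow(all_tests), 4)
  for (r in seq_len(nrow(all_tests))) {
    expect_equal(all_tests$p_value[r],
                 oracle_hyper_upper(20, all_tests$j[r], all_tests$n[r], all_tests$x[r]),
                 tolerance = 1e-12)
  }
  expect_equal(all_tests$p_adjust, oracle_bh(all_tests$p_value), tolerance = 1e-12)
})

test_that("planted miRNA-pathway pairs are retained and decoys are not", {
  b <- generate_bundle(small_config(seed = 13))
  cons <- build_consensus(b$predictions, k = 4)
  planted <- dplyr::filter(b$pathways, pathway %in% b$truth$planted_pathways)
  pairs <- mirna_pathway_enrichment(cons, planted, universe = b$universe,
                                    alpha = 0.01)
  truth <- paste(b$truth$planted_pairs$mirna, b$truth$planted_pairs$pathway)
  got <- paste(pairs$mirna, pairs$pathway)
  expect_gte(mean(truth %in% got), 0.95)
  expect_equal(sum(!(got %in% truth)), 0)
})

test_that("per-miRNA FDR scope corrects within each miRNA family of tests", {
  b <- generate_bundle(small_config(seed = 13))
  cons <- build_consensus(b$predictions, k = 4)
  planted <- dplyr::filter(b$pathways, pathway %in% b$truth$planted_pathways)
  per <- mirna_pathway_enrichment(cons, planted, universe = b$universe,
                                  fdr_scope = "per_mirna", keep_all = TRUE)
  one <- dplyr::filter(per, mirna == per$mirna[1])
  expect_equal(one$p_adjust, oracle_bh(one$p_value), tolerance = 1e-12)
})

test_that("distinct miRNA/pathway counts recomputed from pairs are consistent", {
  b <- generate_bundle(small_config(seed = 13))
  cons <- build_consensus(b$predictions, k = 4)
  planted <- dplyr::filter(b$pathways, pathway %in% b$truth$planted_pathways)
  pairs <- mirna_pathway_enrichment(cons, planted, universe = b$universe)
  expect_equal(dplyr::n_distinct(pairs$mirna), length(unique(pairs$mirna)))
  expect_true(all(pairs$p_adjust < 0.01))
  counts <- consensus_target_counts(cons)
  expect_equal(sum(counts$n_targets), nrow(cons))
})
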