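test_that("GMT files parse into validated collections", {
  path <- write_tmp_gmt(c("p1\tfirst set\ta\tb\tc", "p2\tsecond set\tC\td"))
  col <- read_gmt(path)
  expect_equal(col$pathway, c("p1", "p2"))
  expect_equal(col$genes, list(c("A", "B", "C"), c("C", "D")))
  expect_setequal(pathway_universe(col), c("A", "B", "C", "D"))
})

test_that("GMT parse errors carry location and cause", {
  expect_error(read_gmt(write_tmp_gmt(character(0))), "no gene sets")
  expect_error(read_gmt(write_tmp_gmt(c("p1\tok\ta", "p2\tonly-two-fields"))),
               "line 2")
  expect_error(read_gmt(write_tmp_gmt(c("p1\tx\ta", "p1\ty\tb"))),
               "duplicate pathway id")
})

test_that("write_gmt / read_gmt round-trips canonical content", {
  col <- make_collection(list(pw1 = c("A", "B"), pw2 = c("B", "C", "D")),
                         categories = c("cat one", NA))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(col, path)
  back <- read_gmt(path)
  expect_equal(back$pathway, col$pathway)
  expect_equal(back$genes, col$genes)
  expect_equal(back$category, col$category)
  # duplicate genes collapse to canonical form on read
  path2 <- write_tmp_gmt("p\tdesc\ta\tA\tb")
  expect_equal(read_gmt(path2)$genes[[1]], c("A", "B"))
})

test_that("prediction readers merge, deduplicate and validate sources", {
  dir <- withr::local_tempdir()
  for (s in c("toolA", "toolB", "toolC", "toolD")) {
    writeLines(c("miR-x\tg1", "miR-x\tg1", "miR-y\tg2"),
               file.path(dir, paste0(s, ".tsv")))
  }
  pred <- read_predictions(list.files(dir, full.names = TRUE))
  # same pair in 4 files -> 4 sources; in-file duplicate counted once
  expect_equal(nrow(pred), 8)
  expect_equal(sum(pred$mirna == "hsa-mir-x" & pred$gene == "G1"), 4)
  expect_error(read_predictions(list.files(dir, full.names = TRUE),
                                roster = c("toolA", "toolB")),
               "not in the declared roster")
  bad <- file.path(dir, "toolE.tsv")
  writeLines("miR-x\tg1\textra", bad)
  expect_error(read_predictions(bad), "line 1")
})

test_that("miRSNP tables enforce their schema", {
  tab <- mirsnp_records(
    list("rs1", "target_site", "miR-a", "g1", "db1", TRUE),
    list("rs2", "mirna_gene", "miR-b", NA, "db2", FALSE)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  out <- read_mirsnp_table(path)
  expect_equal(out$mirna, c("hsa-mir-a", "hsa-mir-b"))
  expect_equal(out$gene, c("G1", NA))
  expect_equal(out$validated, c(TRUE, FALSE))

  bad <- tab; bad$rsid[1] <- "snp1"
  readr::write_tsv(bad, path)
  expect_error(read_mirsnp_table(path), "rs\\[0-9\\]")
  bad <- tab; bad$gene[1] <- NA
  readr::write_tsv(bad, path)
  expect_error(read_mirsnp_table(path), "target_site")
  readr::write_tsv(tab, path)
  expect_error(read_mirsnp_table(path, target_site_roster = "other"), "roster")
})

test_that("gene lists reject duplicates and keep evidence text", {
  path <- withr::local_tempfile()
  writeLines(c("igf1r\tevidence note", "BDNF"), path)
  gl <- read_gene_list(path)
  expect_equal(gl$gene, c("IGF1R", "BDNF"))
  expect_equal(gl$evidence, c("evidence note", NA))
  writeLines(c("A", "a"), path)
  expect_error(read_gene_list(path), "duplicate gene")
})

test_that("miRNA identifiers normalize to lowercase hsa- names", {
  expect_equal(normalize_mirna(c("miR-15b", "hsa-miR-16", "HSA-MIR-195")),
               c("hsa-mir-15b", "hsa-mir-16", "hsa-mir-195"))
})

test_that("network writers emit GraphML and edge TSV, including empty graphs", {
  g <- igraph::make_graph(c("a", "b", "b", "c"), directed = FALSE)
  dir <- withr::local_tempdir()
  write_network(g, file.path(dir, "g.graphml"))
  expect_true(file.size(file.path(dir, "g.graphml")) > 0)
  empty <- igraph::make_empty_graph(n = 0, directed = FALSE)
  write_network(empty, file.path(dir, "empty.graphml"))
  reread <- igraph::read_graph(file.path(dir, "empty.graphml"), format = "graphml")
  expect_equal(igraph::ecount(reread), 0)
  write_network(g, file.path(dir, "g.tsv"), format = "tsv")
  expect_equal(nrow(readr::read_tsv(file.path(dir, "g.tsv"), show_col_types = FALSE)), 2)
})

test_that("the packaged risk-pathway enrichment fixture matches the published table", {
  tab <- load_psd_enrichment_fixture()
  expect_equal(nrow(tab), 22)
  expect_equal(tab$p_adjust[tab$pathway == "hsa04066"], 9.13e-05)
  # every printed row clears the 0.01 adjusted-p threshold
  expect_equal(sum(tab$p_adjust < 0.01), nrow(tab))
  expect_equal(max(tab$p_adjust), 0.009841294)
})
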