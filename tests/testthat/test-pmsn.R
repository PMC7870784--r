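fixture_pairs <- function() {
  tibble::tibble(
    mirna = c("hsa-mir-a", "hsa-mir-a", "hsa-mir-b"),
    pathway = c("p1", "p2", "p1"),
    p_adjust = c(1e-6, 1e-4, 1e-3)
  )
}

fixture_collection <- function() {
  make_collection(list(p1 = c("G1", "G2"), p2 = c("G3", "G4"), p3 = "G9"))
}

test_that("PMSN assembly annotates edges and nodes by the membership rule", {
  ts <- tibble::tibble(rsid = c("rs1", "rs2", "rs3"),
                       mirna = c("hsa-mir-a", "hsa-mir-a", "hsa-mir-b"),
                       gene = c("G1", "G9", "G3"))
  mg <- tibble::tibble(rsid = c("rs10", "rs11"),
                       mirna = c("hsa-mir-b", "hsa-mir-z"))
  net <- build_pmsn(fixture_pairs(), fixture_collection(),
                    target_site_snps = ts, mirna_gene_snps = mg)
  # rs1: edge (mir-a, p1) exists and G1 in p1 -> annotates that edge
  expect_equal(nrow(net$edge_snps), 1)
  expect_equal(net$edge_snps$rsid, "rs1")
  expect_equal(net$edge_snps$pathway, "p1")
  # rs2: G9 is in no pathway linked to mir-a; rs3: no (mir-b, p2) edge and
  # G3 not in p1 -> both reported unattached, with the absent mirna_gene SNP
  expect_setequal(net$unattached$rsid, c("rs2", "rs3", "rs11"))
  expect_equal(net$node_snps$rsid, "rs10")
  # annotation rule re-checked by exhaustive scan
  membership <- tidyr::unnest(dplyr::select(fixture_collection(), pathway, genes),
                              genes)
  for (r in seq_len(nrow(ts))) {
    for (e in seq_len(nrow(fixture_pairs()))) {
      should <- ts$mirna[r] == fixture_pairs()$mirna[e] &&
        any(membership$pathway == fixture_pairs()$pathway[e] &
              membership$genes == ts$gene[r])
      got <- any(net$edge_snps$rsid == ts$rsid[r] &
                   net$edge_snps$mirna == fixture_pairs()$mirna[e] &
                   net$edge_snps$pathway == fixture_pairs()$pathway[e])
      expect_equal(got, should)
    }
  }
})

test_that("PMSN is bipartite with exact degree bookkeeping", {
  net <- build_pmsn(fixture_pairs(), fixture_collection())
  expect_equal(nrow(net$edge_snps), 0)
  top <- pmsn_topology(net)
  expect_equal(sum(top$nodes$degree), 2 * nrow(net$edges))
  mirna_deg <- sum(top$nodes$degree[top$nodes$type == "mirna"])
  path_deg <- sum(top$nodes$degree[top$nodes$type == "pathway"])
  expect_equal(mirna_deg, nrow(net$edges))
  expect_equal(path_deg, nrow(net$edges))
  expect_error(build_pmsn(dplyr::mutate(fixture_pairs(), pathway = "nope"),
                          fixture_collection()),
               "unknown pathway")
})

test_that("star and path betweenness match closed forms", {
  star <- tibble::tibble(mirna = "hsa-mir-hub", pathway = paste0("p", 1:4),
                         p_adjust = 1e-5)
  col <- make_collection(setNames(as.list(paste0("G", 1:4)), paste0("p", 1:4)))
  top <- pmsn_topology(build_pmsn(star, col))
  hub <- top$nodes[top$nodes$node == "hsa-mir-hub", ]
  expect_equal(hub$degree, 4L)
  expect_equal(hub$betweenness, 1)
  expect_equal(top$nodes$betweenness[top$nodes$type == "pathway"], rep(0, 4))

  path3 <- tibble::tibble(mirna = c("hsa-mir-m", "hsa-mir-m2"),
                          pathway = c("mid", "mid"), p_adjust = 1e-5)
  col3 <- make_collection(list(mid = "G1"))
  top3 <- pmsn_topology(build_pmsn(path3, col3))
  expect_equal(top3$nodes$betweenness[top3$nodes$node == "mid"], 1)
})

test_that("betweenness equals a path-enumeration oracle on random bipartite graphs", {
  set.seed(99)
  for (rep in 1:12) {
    nl <- sample(3:12, 1); nr <- sample(3:12, 1)
    adj <- random_bipartite_adj(nl, nr, p_edge = stats::runif(1, 0.15, 0.5))
    keep <- rowSums(adj) > 0
    if (sum(keep) < 4) next
    adj <- adj[keep, keep, drop = FALSE]
    names <- c(paste0("hsa-mir-", seq_len(nl)), paste0("pw", seq_len(nr)))[keep]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- names
    igraph::V(g)$type <- ifelse(startsWith(names, "hsa-"), "mirna", "pathway")
    top <- pmsn_topology(g)
    want <- oracle_betweenness(adj)
    expect_equal(top$nodes$betweenness[match(names, top$nodes$node)], want,
                 tolerance = 1e-12)
  }
})

test_that("power-law fit recovers an exactly constructed exponent-2 histogram", {
  # counts 100/d^2 are exact integers at these degrees, so the log-log line
  # has slope exactly -2
  hist <- tibble::tibble(degree = c(1L, 2L, 5L, 10L), count = c(100L, 25L, 4L, 1L))
  fit <- fit_powerlaw(hist)
  expect_equal(fit$exponent, 2, tolerance = 0.05)
  expect_gte(fit$r_squared, 0.99)
  # MLE flag returns a finite exponent as well
  mle <- fit_powerlaw(hist, method = "mle")
  expect_true(is.finite(mle$exponent))
  # degenerate single-bin histogram cannot be fit
  expect_true(is.na(fit_powerlaw(tibble::tibble(degree = 3L, count = 5L))$exponent))
})

test_that("hub report ranks miRNAs above the degree threshold and all pathways", {
  pairs <- dplyr::bind_rows(
    tibble::tibble(mirna = "hsa-mir-big", pathway = paste0("p", 1:10), p_adjust = 1e-8),
    tibble::tibble(mirna = "hsa-mir-small", pathway = "p1", p_adjust = 1e-3)
  )
  col <- make_collection(setNames(as.list(paste0("G", 1:10)), paste0("p", 1:10)))
  top <- pmsn_topology(build_pmsn(pairs, col))
  hubs <- hub_report(top, min_degree = 3)
  expect_equal(hubs$mirnas$node, "hsa-mir-big")
  expect_equal(hubs$mirnas$degree, 10L)
  expect_equal(nrow(hubs$pathways), 10)
  expect_equal(hubs$pathways$node[1], "p1") # degree 2 beats all degree-1 ties
  none <- hub_report(top, min_degree = 10)
  expect_equal(nrow(none$mirnas), 0)
})

test_that("planted hub structure is recovered from synthetic data", {
  b <- generate_bundle(small_config(seed = 17))
  run <- run_pipeline(b)
  truth_deg <- table(b$truth$planted_pairs$mirna)
  hubs <- hub_report(run$topology, min_degree = 3)
  expect_setequal(hubs$mirnas$node, names(truth_deg)[truth_deg > 3])
  expect_equal(hubs$mirnas$degree,
               unname(as.integer(truth_deg[hubs$mirnas$node])))
})

test_that("tidy and glance summarize networks consistently", {
  net <- build_pmsn(fixture_pairs(), fixture_collection())
  expect_equal(nrow(tidy(net)), 3)
  g <- glance(net)
  expect_equal(g$n_mirnas, 2L)
  expect_equal(g$n_pathways, 2L)
  top <- pmsn_topology(net)
  expect_equal(glance(top)$n_edges, 3)
  expect_equal(nrow(tidy(top)), 4)
})
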