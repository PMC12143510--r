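test_that("the worked toy network reproduces the hand-traced centralities", {
  g <- toy_ppi()
  rk <- rank_drivers("S", g, toy_degs())
  expect_equal(rk$K, 2L)
  expect_equal(rk$N, 1)
  expect_equal(rk$Q, 2)
  expect_equal(rk$alpha_used, 0.5)
  expect_equal(rk$C_WL, 2.0)
  expect_equal(rk$EGIS, 9.0)
  expect_equal(rk$rank, 1L)
})

test_that("degree centrality reads the full reference network", {
  star <- ppi_graph(ppi_edges(data.frame(
    gene_a = "hub", gene_b = paste0("leaf", 1:5), confidence = 900)))
  expect_equal(degree_K(star, "hub"), 5L)
  expect_equal(degree_K(star, "leaf1"), 1L)
  iso <- ppi_graph(ppi_edges(data.frame(gene_a = "a", gene_b = "b",
                                        confidence = 900)),
                   nodes = "lonely")
  expect_equal(degree_K(iso, "lonely"), 0L)
  tri <- ppi_graph(ppi_edges(data.frame(gene_a = c("a", "b", "c"),
                                        gene_b = c("b", "c", "a"),
                                        confidence = 900)))
  expect_equal(degree_K(tri, "a"), 2L)
  expect_error(degree_K(tri, "zz"), "not in the PPI")
})

test_that("local networks include exactly sources, 2-hop DEGs and bridges", {
  chain <- ppi_graph(ppi_edges(data.frame(gene_a = c("S", "u"),
                                          gene_b = c("u", "d"),
                                          confidence = 900)))
  ln <- build_local_network(chain, "S", "d")
  expect_setequal(ln$nodes$gene_id, c("S", "u", "d"))
  expect_equal(ln$nodes$role[ln$nodes$gene_id == "u"], "intermediate")
  expect_equal(ln$nodes$role[ln$nodes$gene_id == "d"], "target")

  # a one-hop DEG bridging to a two-hop DEG carries both roles
  path2 <- ppi_graph(ppi_edges(data.frame(gene_a = c("S", "d1"),
                                          gene_b = c("d1", "d2"),
                                          confidence = 900)))
  ln2 <- build_local_network(path2, "S", c("d1", "d2"))
  expect_equal(ln2$nodes$role[ln2$nodes$gene_id == "d1"],
               "intermediate+target")
  expect_equal(ln2$nodes$role[ln2$nodes$gene_id == "d2"], "target")

  # a one-hop non-DEG with no DEG behind it is excluded
  dangler <- ppi_graph(ppi_edges(data.frame(gene_a = "S", gene_b = "x",
                                            confidence = 900)))
  ln3 <- build_local_network(dangler, "S", character())
  expect_equal(ln3$nodes$gene_id, "S")
  expect_error(build_local_network(dangler, "nope", "x"), "not in the PPI")
})

test_that("node-inclusion rule matches brute force on all small graphs", {
  # exhaustive check over every labelled 4-node graph
  ids <- c("S", "a", "b", "c")
  pairs <- t(combn(4, 2))
  for (mask in 0:63) {
    on <- bitwAnd(mask, 2^(0:5)) > 0
    if (!any(on)) next
    adj <- matrix(0L, 4, 4, dimnames = list(ids, ids))
    for (k in which(on)) {
      adj[pairs[k, 1], pairs[k, 2]] <- 1L
      adj[pairs[k, 2], pairs[k, 1]] <- 1L
    }
    edges <- data.frame(gene_a = ids[pairs[on, 1]],
                        gene_b = ids[pairs[on, 2]], confidence = 900)
    g <- ppi_graph(ppi_edges(edges), nodes = ids)
    for (deg_mask in c(0L, 2L, 6L, 14L)) {
      deg <- ids[c(FALSE, bitwAnd(deg_mask, c(2L, 4L, 8L)) > 0)]
      got <- sort(build_local_network(g, "S", deg)$nodes$gene_id)
      # expected node set recomputed directly from the adjacency matrix
      nb1 <- ids[adj["S", ] == 1]
      rest <- setdiff(ids, c("S", nb1))
      hop2 <- rest[vapply(rest, function(w) any(adj[w, nb1] == 1), logical(1))]
      d2 <- intersect(hop2, deg)
      bridges <- nb1[vapply(nb1, function(u) any(adj[u, d2] == 1), logical(1))]
      want <- sort(unique(c("S", intersect(nb1, deg), d2, bridges)))
      expect_equal(got, want)
    }
  }
})

test_that("N and Q follow their definitions on enumerated cases", {
  g <- toy_ppi()
  expect_equal(nearest_deg_count(g, "S", toy_degs()), 1L)
  expect_equal(nearest_deg_count(g, "u1", toy_degs()), 2L)
  expect_equal(q_value(g, "S", toy_degs()), 2L)  # N(u1)=2 + N(d1)=0
  iso <- ppi_graph(ppi_edges(data.frame(gene_a = "a", gene_b = "b",
                                        confidence = 900)), nodes = "z")
  expect_equal(nearest_deg_count(iso, "z", "a"), 0L)
  expect_equal(q_value(iso, "z", "a"), 0L)
  # 3-clique with both neighbors of S DEGs adjacent to each other
  tri <- ppi_graph(ppi_edges(data.frame(gene_a = c("S", "S", "da"),
                                        gene_b = c("da", "db", "db"),
                                        confidence = 900)))
  expect_equal(q_value(tri, "S", c("da", "db")), 2L)  # N(da)=N(db)=1
})

test_that("alpha, C_WL and EGIS compute the closed forms with guards", {
  expect_equal(alpha_weight(1, 2), 0.5)
  expect_equal(alpha_weight(c(0, 0), c(4, 6)), 0)   # zero numerator
  expect_equal(alpha_weight(c(2, 1), c(0, 0)), 0)   # zero-denominator guard
  expect_error(alpha_weight(numeric(), numeric()), "empty")
  expect_equal(c_wl(1, 2, 0.5), 2.0)
  expect_equal(c_wl(3, 0, 0.7), 3)
  expect_equal(c_wl(0, 0, 1), 0)
  expect_equal(egis(2, 2.0), 9.0)
  expect_equal(egis(0, 0), 1.0)
  expect_true(egis(3, 2) > egis(2, 2) && egis(2, 3) > egis(2, 2))
})

test_that("pipeline centralities equal brute-force re-evaluation", {
  worst <- 0
  for (seed in 1:100) {
    n <- 10 + (seed %% 41)
    fx <- random_graph_fixture(n, p_edge = 0.1 + (seed %% 5) / 25, seed = seed)
    g <- ppi_graph(ppi_edges(fx$edges), nodes = fx$ids)
    rk <- suppressWarnings(rank_drivers(fx$edg_genes, g, fx$deg_genes,
                                        top_m = 100))
    ora <- oracle_centrality(fx$adj, fx$deg_genes, fx$edg_genes)
    rk <- rk[order(rk$gene_id), ]
    ora <- ora[order(ora$gene_id), ]
    expect_equal(rk$gene_id, ora$gene_id)
    dev <- max(abs(rk$K - ora$K), abs(rk$N - ora$N), abs(rk$Q - ora$Q),
               abs(rk$alpha_used - ora$alpha), abs(rk$C_WL - ora$C_WL),
               abs(rk$EGIS - ora$EGIS))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-12)
})

test_that("bounds hold: C_WL >= N, EGIS >= K+1, alpha >= 0", {
  for (seed in c(5, 17, 33)) {
    fx <- random_graph_fixture(30, seed = seed)
    g <- ppi_graph(ppi_edges(fx$edges), nodes = fx$ids)
    rk <- rank_drivers(fx$edg_genes, g, fx$deg_genes)
    expect_true(all(rk$C_WL >= rk$N))
    expect_true(all(rk$EGIS >= rk$K + 1))
    expect_true(all(rk$alpha_used >= 0))
  }
})

test_that("removing a DEG label never increases N or Q", {
  for (seed in c(4, 8, 15)) {
    fx <- random_graph_fixture(25, seed = seed)
    if (length(fx$deg_genes) == 0) next
    g <- ppi_graph(ppi_edges(fx$edges), nodes = fx$ids)
    full <- rank_drivers(fx$edg_genes, g, fx$deg_genes)
    reduced_set <- fx$deg_genes[-1]
    red <- if (length(reduced_set) > 0) {
      rank_drivers(fx$edg_genes, g, reduced_set)
    } else {
      suppressWarnings(rank_drivers(fx$edg_genes, g, character()))
    }
    full <- full[order(full$gene_id), ]
    red <- red[order(red$gene_id), ]
    expect_true(all(red$N <= full$N))
    expect_true(all(red$Q <= full$Q))
    # at the fixed original alpha, C_WL and EGIS are monotone too
    expect_true(all(c_wl(red$N, red$Q, full$alpha_used[1]) <= full$C_WL))
  }
})

test_that("ranking is a gap-free permutation with documented tie-breaks", {
  fx <- random_graph_fixture(40, seed = 23)
  g <- ppi_graph(ppi_edges(fx$edges), nodes = fx$ids)
  rk <- rank_drivers(fx$edg_genes, g, fx$deg_genes, top_m = 3)
  expect_equal(sort(rk$rank), seq_len(nrow(rk)))
  expect_equal(sum(rk$candidate), min(3, nrow(rk)))
  expect_equal(nrow(rk), length(unique(rk$gene_id)))
  # EGIS+K ties resolve by ascending gene id
  twin <- ppi_graph(ppi_edges(data.frame(gene_a = c("bb", "aa"),
                                         gene_b = c("x", "y"),
                                         confidence = 900)))
  rk2 <- suppressWarnings(rank_drivers(c("bb", "aa"), twin, character()))
  expect_equal(rk2$gene_id, c("aa", "bb"))
})

test_that("with no DEGs the ranking degenerates to degree order", {
  fx <- random_graph_fixture(30, seed = 12)
  g <- ppi_graph(ppi_edges(fx$edges), nodes = fx$ids)
  expect_warning(rk <- rank_drivers(fx$edg_genes, g, character()),
                 "no gene passes")
  expect_true(all(rk$C_WL == 0))
  expect_equal(rk$EGIS, rk$K + 1)
  expect_false(is.unsorted(rev(rk$K)))
  expect_error(rank_drivers("not_in_graph", g, fx$deg_genes), "no EDG")
})

test_that("DEG filtering uses the strict printed thresholds", {
  tab <- data.frame(gene_id = c("at_lfc", "above", "at_q", "ok", "list_na"),
                    log2FC = c(1.0, 1.01, 2, -2, 3),
                    q_value = c(0.001, 0.001, 0.01, 0.009, 0.5))
  expect_setequal(deg_gene_set(tab), c("above", "ok"))
  lst <- data.frame(gene_id = c("a", "b"), log2FC = NA_real_,
                    q_value = NA_real_)
  expect_setequal(deg_gene_set(lst), c("a", "b"))
})
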