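# PPI graph construction, the four centralities, median-filter core
# extraction. Exhaustive oracle equivalence lives in test-acceptance.R;
# here: hand-checkable cases and structural properties.

path3 <- function() graph_from_adj(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
                                   c("A", "B", "C"))

star5 <- function() {
  A <- matrix(0L, 5, 5); A[1, 2:5] <- 1L; A <- A + t(A)
  graph_from_adj(A, c("A", "L1", "L2", "L3", "L4"))  # A is the hub
}

test_that("ppi_graph thresholds inclusively and keeps a simple graph", {
  e <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                  score = c(0.85, 0.90, 0.95))
  g <- ppi_graph(e, min_score = 0.9)
  expect_equal(graph_size(g), 2L)           # >= is inclusive
  expect_false("A" %in% g$nodes)            # dropped edge leaves no orphan

  dup <- data.frame(a = c("X", "Y"), b = c("Y", "X"), score = c(0.91, 0.99))
  g2 <- ppi_graph(dup, min_score = 0.9)
  expect_equal(graph_size(g2), 1L)
  expect_equal(graph_edges(g2)$score, 0.99) # duplicates keep max score

  loop <- data.frame(a = "A", b = "a", score = 1)  # self-loop after casefold
  expect_equal(graph_size(ppi_graph(loop, 0)), 0L)

  expect_error(ppi_graph(data.frame(a = "A", b = "B", score = 1.2), 0.5),
               "\\[0, 1\\]")
  expect_error(ppi_graph(e, min_score = 2), "min_score")
})

test_that("degree matches hand values and the row-sum oracle", {
  expect_equal(centrality_degree(path3()),
               c(A = 1L, B = 2L, C = 1L))
  K5 <- graph_from_adj(matrix(1L, 5, 5) - diag(5L))
  expect_true(all(centrality_degree(K5) == 4L))
  set.seed(7)
  A <- random_adj(20, 0.3)
  g <- graph_from_adj(A)
  expect_equal(unname(centrality_degree(g)), unname(rowSums(A)))
  expect_equal(sum(centrality_degree(g)), 2L * graph_size(g))
})

test_that("betweenness matches hand-enumerated path counts", {
  expect_equal(centrality_betweenness(path3()), c(A = 0, B = 1, C = 0))
  # star: all 6 leaf pairs route through the hub
  expect_equal(centrality_betweenness(star5()),
               c(A = 6, L1 = 0, L2 = 0, L3 = 0, L4 = 0))
})

test_that("closeness is component-wise with (|C|-1)/sum(d)", {
  expect_equal(centrality_closeness(star5())[["A"]], 1)
  expect_equal(unname(centrality_closeness(path3())), c(2/3, 1, 2/3))
  # two disjoint triangles: every node sees its component at distance 1
  A <- matrix(0L, 6, 6)
  A[1, 2] <- A[1, 3] <- A[2, 3] <- A[4, 5] <- A[4, 6] <- A[5, 6] <- 1L
  A <- A + t(A)
  expect_true(all(centrality_closeness(graph_from_adj(A)) == 1))
})

test_that("eigenvector centrality matches the dense eigensolver", {
  K4 <- graph_from_adj(matrix(1L, 4, 4) - diag(4L))
  expect_equal(unname(centrality_eigenvector(K4)), rep(1, 4),
               tolerance = 1e-9)
  # star K_{1,4}: hub 1, leaves 1/2 (principal eigenvalue 2)
  expect_equal(unname(centrality_eigenvector(star5())),
               c(1, 0.5, 0.5, 0.5, 0.5), tolerance = 1e-8)
  set.seed(13)
  repeat {                                   # a random *connected* graph
    A <- random_adj(15, 0.25)
    if (adj_connected(A)) break
  }
  g <- graph_from_adj(A)
  expect_equal(unname(centrality_eigenvector(g)),
               oracle_centralities(A)$ec, tolerance = 1e-6)
  expect_error(centrality_eigenvector(path3(), tol = 1e-16, max_iter = 2L),
               class = "netpharm_no_convergence")
})

test_that("centralities are invariant under node relabeling", {
  set.seed(17)
  A <- random_adj(12, 0.3)
  g <- graph_from_adj(A)
  perm <- sample(12)
  relabeled <- sprintf("N%02d", perm)        # permuted names, same topology
  g2 <- graph_from_adj(A, relabeled)
  for (fn in list(centrality_degree, centrality_betweenness,
                  centrality_closeness)) {
    v1 <- fn(g)
    v2 <- fn(g2)
    expect_equal(unname(v2[sprintf("N%02d", perm)]),
                 unname(v1[sprintf("N%02d", 1:12)]), tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases endpoint degrees", {
  set.seed(19)
  A <- random_adj(10, 0.2)
  miss <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
  pick <- miss[sample(nrow(miss), 1), ]
  B <- A; B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- 1L
  d1 <- centrality_degree(graph_from_adj(A))
  d2 <- centrality_degree(graph_from_adj(B))
  expect_true(all(d2 >= d1))
  expect_equal(unname(d2[pick] - d1[pick]), c(1L, 1L))
})

test_that("median_filter_round keeps strict above-median nodes", {
  # path on 4 nodes: degrees 1,2,2,1; median 1.5 -> middle nodes survive
  A <- matrix(0L, 4, 4); A[1, 2] <- A[2, 3] <- A[3, 4] <- 1L; A <- A + t(A)
  g <- graph_from_adj(A, c("A", "B", "C", "D"))
  kept <- median_filter_round(g, metrics = "dc")
  expect_equal(kept$nodes, c("B", "C"))
  expect_equal(attr(kept, "medians")[["dc"]], 1.5)
  # all-tie graph: strict inequality empties it
  tri <- graph_from_adj(matrix(1L, 3, 3) - diag(3L))
  expect_equal(length(median_filter_round(tri)$nodes), 0L)
  # never increases node count
  set.seed(23)
  for (rep in 1:10) {
    A <- random_adj(12, stats::runif(1, 0.2, 0.6))
    g <- graph_from_adj(A)
    out <- median_filter_round(g, metrics = c("dc", "bc"))
    expect_lt(length(out$nodes), length(g$nodes))  # strict > median drops >= half
  }
})

test_that("extract_core composes rounds, is deterministic, flags early stop", {
  A <- matrix(0L, 4, 4); A[1, 2] <- A[2, 3] <- A[3, 4] <- 1L; A <- A + t(A)
  g <- graph_from_adj(A, c("A", "B", "C", "D"))
  one <- extract_core(g, metrics = "dc", rounds = 1)
  expect_equal(sort(one$core_nodes),
               sort(median_filter_round(g, "dc")$nodes))
  # two manual applications == rounds = 2
  cfg <- synth_config(seed = 5)
  fx <- gen_ppi(cfg, tempfile("ppi"))
  big <- ppi_graph(read_ppi_edges(fx$path), min_score = 0)
  manual <- median_filter_round(median_filter_round(big))
  auto <- extract_core(big, rounds = 2)
  expect_equal(sort(auto$core_nodes), sort(manual$nodes))
  expect_false(auto$exhausted)
  # ranked by degree descending with name tie-break, deterministically
  dc <- centrality_degree(auto$graph)
  expect_equal(auto$core_nodes, names(dc)[order(-as.numeric(dc), names(dc))])
  expect_identical(extract_core(big, rounds = 2)$core_nodes, auto$core_nodes)
  # more rounds than the graph supports -> early stop, previous core kept
  deep <- extract_core(g, metrics = "dc", rounds = 5)
  expect_true(deep$exhausted)
  expect_equal(sort(deep$core_nodes), c("B", "C"))
  expect_error(extract_core(g, rounds = 0), "rounds")
})

test_that("centralities agree with igraph on random connected graphs", {
  set.seed(29)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    repeat {
      A <- random_adj(n, stats::runif(1, 0.2, 0.5))
      if (adj_connected(A)) break
    }
    g <- graph_from_adj(A)
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(unname(centrality_degree(g)), igraph::degree(ig))
    expect_equal(unname(centrality_betweenness(g)),
                 igraph::betweenness(ig), tolerance = 1e-9)
    expect_equal(unname(centrality_closeness(g)),
                 igraph::closeness(ig, normalized = TRUE), tolerance = 1e-9)
    expect_equal(unname(centrality_eigenvector(g)),
                 unname(igraph::eigen_centrality(ig)$vector),
                 tolerance = 1e-6)
  }
})

test_that("induced subgraph restricts nodes and edges coherently", {
  e <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "A"), score = 1)
  g <- ppi_graph(e, 0)
  sub <- induced_subgraph(g, c("A", "B"))
  expect_equal(sub$nodes, c("A", "B"))
  expect_equal(graph_size(sub), 1L)
  expect_equal(length(induced_subgraph(g, character(0))$nodes), 0L)
})
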