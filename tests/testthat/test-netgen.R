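test_that("Erdos-Renyi generator returns exactly n nodes and m edges", {
  set.seed(101)
  g <- generate_random_graph(1000, 2000)
  expect_equal(igraph::vcount(g), 1000)
  expect_equal(igraph::ecount(g), 2000)
  expect_true(igraph::is_simple(g))
  # only one simple graph has 6 edges on 4 nodes: the complete graph
  k4 <- generate_random_graph(4, 6)
  expect_equal(igraph::degree(k4), rep(3, 4))
  expect_error(generate_random_graph(4, 7), "possible edges")
  for (s in 1:5) {
    set.seed(s)
    expect_equal(mean(igraph::degree(generate_random_graph(500, 1000))), 4)
  }
})

test_that("Barabasi-Albert generator grows a tree from a single node", {
  set.seed(102)
  g <- generate_barabasi_albert(1000)
  expect_equal(igraph::ecount(g), 999)
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_tree(g))
  expect_equal(avg_clustering(g), 0)
  expect_equal(count_communities(g), 1)
})

test_that("Watts-Strogatz generator keeps the lattice edge count", {
  set.seed(103)
  g <- generate_watts_strogatz(1000, 4, 0.1)
  expect_equal(igraph::ecount(g), 2000)
  expect_true(igraph::is_simple(g))
  g0 <- generate_watts_strogatz(1000, 4, 0)
  expect_equal(avg_clustering(g0), 0.5)  # 3(k-2)/(4(k-1)) at k = 4
  expect_error(generate_watts_strogatz(100, 3, 0.1), "even")
  expect_error(generate_watts_strogatz(100, 102, 0.1), "smaller than n")
  # full rewiring destroys the lattice's long paths
  set.seed(104)
  d1 <- igraph::mean_distance(generate_watts_strogatz(500, 4, 1))
  d0 <- igraph::mean_distance(generate_watts_strogatz(500, 4, 0))
  expect_lt(d1, d0)
})

test_that("static scale-free generator yields m edges and heavy tails", {
  set.seed(105)
  g <- generate_scale_free(1000, 2000, 2)
  expect_equal(igraph::ecount(g), 2000)
  expect_true(igraph::is_simple(g))
  expect_error(generate_scale_free(10, 100), "possible edges")
  # heavier degree tail than G(n, m) at matched size
  vs <- replicate(30, {
    c(var(igraph::degree(generate_scale_free(400, 800, 2))),
      var(igraph::degree(generate_random_graph(400, 800))))
  })
  expect_gt(mean(vs[1, ]), mean(vs[2, ]))
  # at large alpha the weights flatten and the model approaches G(n, m)
  set.seed(106)
  vflat <- mean(replicate(30, var(igraph::degree(
    generate_scale_free(400, 800, alpha = 1e6)))))
  expect_equal(vflat, mean(vs[2, ]), tolerance = 0.1)
})

test_that("stochastic block model follows the block recipe", {
  set.seed(107)
  out <- generate_sbm(1000, 20)
  expect_equal(sum(out$spec$block_sizes), 1000)
  expect_equal(igraph::vcount(out$graph), 1000)
  W <- out$spec$weight_matrix
  expect_identical(W, t(W))
  sz <- out$spec$block_sizes
  pos <- sz > 0
  expect_true(all(diag(W)[pos] >= 0.01 * sz[pos] - 1e-12 &
                    diag(W)[pos] <= 0.05 * sz[pos] + 1e-12))
  off <- W[upper.tri(W)]
  expect_equal(sum(off == 0), floor(0.6 * length(off)))
  expect_true(all(off[off > 0] >= 1e-4 & off[off > 0] <= 0.01))
  expect_error(generate_sbm(10, 11), "exceed")
  # the zeroed blocks leave the graph disconnected in most draws
  comps <- replicate(20, count_communities(generate_sbm(1000, 20)$graph))
  expect_gt(mean(comps > 1), 0.5)
})

test_that("SNAP edge lists load with loops and duplicates removed", {
  f <- withr::local_tempfile(lines = c("0 1", "1 0", "1 1"))
  g <- load_edge_list(f)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  f2 <- withr::local_tempfile(lines = c("0 1", "2 3"))
  g2 <- load_edge_list(f2)
  expect_equal(igraph::vcount(g2), 4)
  expect_equal(igraph::ecount(g2), 2)
  expect_equal(count_communities(g2), 2)

  f3 <- withr::local_tempfile(lines = c("0 1", "2 x", "3 4"))
  expect_error(load_edge_list(f3), "line 2")
  f4 <- withr::local_tempfile(lines = character(0))
  expect_error(load_edge_list(f4), "empty")
  expect_error(load_edge_list(file.path(tempdir(), "nope.txt")),
               "not found")

  set.seed(108)
  g5 <- generate_random_graph(50, 120)
  f5 <- withr::local_tempfile()
  write_edge_list(g5, f5)
  g6 <- load_edge_list(f5)
  expect_equal(igraph::ecount(g6), 120)
  expect_true(igraph::isomorphic(g5, g6))
})

test_that("induced subsampling preserves structure in expectation", {
  set.seed(109)
  g <- generate_random_graph(200, 400)
  full <- induced_subsample(g, 200)
  expect_equal(igraph::ecount(full), 400)
  expect_equal(sort(igraph::degree(full)), sort(igraph::degree(g)))
  expect_error(induced_subsample(g, 201), "exceeds")
  # E[edges] = m * n(n-1) / (N(N-1))
  m_exp <- 400 * (100 * 99) / (200 * 199)
  sizes <- replicate(200, igraph::ecount(induced_subsample(g, 100)))
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - m_exp), 3 * se + 1e-9)
})

test_that("average clustering matches hand-computed coefficients", {
  k3 <- igraph::make_full_graph(3)
  expect_equal(avg_clustering(k3), 1)
  star <- igraph::make_star(6, mode = "undirected")
  expect_equal(avg_clustering(star), 0)
  # K4 minus one edge: the two degree-2 nodes close their only triangle
  # (coefficient 1), the two degree-3 nodes keep 2 of 3 neighbour pairs
  # linked (coefficient 2/3); mean (1 + 1 + 2/3 + 2/3) / 4 = 5/6
  k4m <- igraph::delete_edges(igraph::make_full_graph(4), 1)
  expect_equal(avg_clustering(k4m), 5 / 6)
  expect_error(avg_clustering(igraph::make_empty_graph(0)), "empty")
})

test_that("community count equals the number of connected components", {
  expect_equal(count_communities(igraph::make_ring(10)), 1)
  expect_equal(count_communities(igraph::make_empty_graph(7,
                                                          directed = FALSE)),
               7)
  set.seed(110)
  expect_equal(count_communities(generate_barabasi_albert(500)), 1)
  expect_gte(count_communities(igraph::make_ring(10), "modularity"), 1)
})

test_that("agent placement follows identity or extraversion rank", {
  set.seed(111)
  star <- igraph::make_star(8, mode = "undirected")  # hub is vertex 1
  ag <- make_agents(8, "personality")
  expect_identical(assign_agents(ag, star, "identity"), 1:8)
  pl <- assign_agents(ag, star, "extraversion_rank")
  expect_equal(pl[1], which.max(ag$extraversion))
  # degree order and extraversion order agree wherever degrees differ
  g <- generate_barabasi_albert(60)
  ag2 <- make_agents(60, "personality")
  pl2 <- assign_agents(ag2, g, "extraversion_rank")
  deg <- igraph::degree(g)
  ext <- ag2$extraversion[pl2]
  for (d in unique(deg)) {
    lower <- ext[deg < d]
    if (length(lower)) expect_true(all(min(ext[deg == d]) >= max(lower)))
  }
  expect_error(assign_agents(make_agents(5, "personality"), star,
                             "extraversion_rank"), "one agent per node")
  expect_error(assign_agents(make_agents(8, "random"), star,
                             "extraversion_rank"), "personality")
})

test_that("seed node is the most central vertex with smallest-id ties", {
  star <- igraph::make_star(9, mode = "undirected")
  expect_equal(pick_seed(star), 1)
  path <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  expect_equal(pick_seed(path), 2)
  ring <- igraph::make_ring(12)
  expect_equal(pick_seed(ring), 1)  # all degrees tie -> smallest id
  expect_equal(pick_seed(star, "betweenness"), 1)
  expect_error(pick_seed(igraph::make_empty_graph(0)), "empty")
})

test_that("generators are deterministic and honour the node count", {
  gens <- list(
    function(n) generate_random_graph(n, 2 * n),
    function(n) generate_barabasi_albert(n),
    function(n) generate_watts_strogatz(n, 4, 0.1),
    function(n) generate_scale_free(n, 2 * n, 2),
    function(n) generate_sbm(n, 5)$graph)
  for (gen in gens) {
    for (n in c(23, 87, 240)) {
      set.seed(n); a <- gen(n)
      set.seed(n); b <- gen(n)
      expect_equal(igraph::vcount(a), n)
      expect_true(igraph::is_simple(a))
      expect_identical(igraph::as_edgelist(a), igraph::as_edgelist(b))
    }
  }
})
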