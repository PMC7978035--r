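test_that("modularity matches hand-evaluated values", {
  g1 <- make_graph(data.frame(from = "a", to = "b", weight = 1))
  expect_equal(modularity_score(g1, c(a = 1, b = 1)), 0)
  expect_equal(modularity_score(g1, c(a = 1, b = 2)), -0.5)

  g2 <- make_graph(data.frame(from = c("a", "c"), to = c("b", "d"),
                              weight = 1))
  expect_equal(modularity_score(g2, c(a = 1, b = 1, c = 2, d = 2)), 0.5)
})

test_that("modularity agrees with the igraph reference implementation", {
  withr::with_seed(21, {
    for (i in 1:10) {
      g <- igraph::sample_gnp(8, 0.5)
      igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 3)
      igraph::V(g)$name <- letters[1:8]
      mem <- sample(1:3, 8, replace = TRUE)
      for (gamma in c(0.5, 1, 2)) {
        expect_equal(modularity_score(g, setNames(mem, letters[1:8]), gamma),
                     igraph::modularity(g, mem, weights = igraph::E(g)$weight,
                                        resolution = gamma),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("clustering reaches sensible optima on canonical graphs", {
  # single edge: one module (Q = 0) beats singletons (Q = -0.5)
  g1 <- make_graph(data.frame(from = "a", to = "b", weight = 1))
  p1 <- cluster_modules(g1, seed = 0)
  expect_equal(p1$n_modules, 1)
  expect_equal(p1$Q, 0)

  # two disjoint complete bipartite K33 blocks: the blocks, any seed
  edges <- rbind(
    expand.grid(from = paste0("f", 1:3), to = paste0("t", 1:3)),
    expand.grid(from = paste0("g", 1:3), to = paste0("u", 1:3)))
  edges$weight <- 1
  g2 <- make_graph(edges)
  truth <- setNames(rep(1:2, each = 6),
                    c(paste0("f", 1:3), paste0("t", 1:3),
                      paste0("g", 1:3), paste0("u", 1:3)))
  for (s in c(0, 7, 123)) {
    p2 <- cluster_modules(g2, seed = s)
    expect_equal(p2$n_modules, 2)
    expect_equal(adjusted_rand(p2$membership, truth), 1)
    expect_equal(p2$Q, 0.5)
  }

  # module ids are dense, 0-based, ordered by decreasing size
  e3 <- data.frame(from = c("a", "a", "a", "x"), to = c("b", "c", "d", "y"),
                   weight = 1)
  p3 <- cluster_modules(make_graph(e3), seed = 1)
  expect_setequal(unique(p3$membership), 0:(p3$n_modules - 1))
  sizes <- as.integer(table(p3$membership))
  expect_true(all(diff(sizes) <= 0))
})

test_that("louvain result matches the exhaustive best partition on small graphs", {
  for (g in small_test_graphs()) {
    A <- adjacency_of(g)
    best <- oracle_best_partition(A, gamma = 1)
    # package formula agrees with the oracle at the oracle's optimum
    expect_equal(modularity_score(g, setNames(best$membership, rownames(A))),
                 best$q, tolerance = 1e-12)
    p <- cluster_modules(g, seed = 0)
    expect_equal(p$Q, best$q, tolerance = 1e-9)
  }
})

test_that("returned Q dominates the trivial partition and ignores weight scale", {
  withr::with_seed(22, {
    for (i in 1:5) {
      sim <- simulate_planted_bipartite(n_modules = 3, n_functions = 9,
                                        n_taxa = 12, p_in = 0.6,
                                        p_out = 0.05, seed = i)
      g <- sim$graph
      p <- cluster_modules(g, seed = i)
      all_one <- setNames(rep(1, igraph::vcount(g)), igraph::V(g)$name)
      expect_gte(p$Q, modularity_score(g, all_one))
      expect_equal(p$Q, modularity_score(g, p$membership, gamma = 1),
                   tolerance = 1e-12)
      # scaling all weights leaves Q and the partition unchanged
      g_scaled <- igraph::set_edge_attr(g, "weight",
                                        value = igraph::E(g)$weight * 7.3)
      p_s <- cluster_modules(g_scaled, seed = i)
      expect_equal(p_s$Q, p$Q, tolerance = 1e-12)
      expect_equal(adjusted_rand(p_s$membership, p$membership), 1)
    }
  })
})

test_that("higher resolution never yields fewer modules", {
  sim <- simulate_planted_bipartite(n_modules = 4, seed = 3)
  counts_prev <- -Inf
  for (gamma in c(0.25, 1, 4, 16, 50)) {
    p <- cluster_modules(sim$graph, gamma = gamma, seed = 3)
    expect_gte(p$n_modules, counts_prev)
    counts_prev <- p$n_modules
  }
  expect_gt(counts_prev, 4) # gamma = 50 shatters the planted blocks
})

test_that("partition errors on nodes missing from membership", {
  g <- make_graph(data.frame(from = "a", to = "b", weight = 1))
  expect_error(modularity_score(g, c(a = 1)), "lacks node")
})
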