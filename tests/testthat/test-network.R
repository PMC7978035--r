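toy_catalog <- function() {
  make_catalog(data.frame(
    pathway = c("aerobic methane oxidation", "acid phosphatase",
                "N assimilation", "dissimilatory sulfate reduction"),
    cycle = c("C", "P", "N", "S"),
    marker_id = c("PF10000", "PF03767", "K10001", "PF13187"),
    db = c("Pfam", "Pfam", "KEGG", "Pfam"), stringsAsFactors = FALSE))
}

toy_counts <- function() {
  data.frame(
    pathway = c(rep("aerobic methane oxidation", 2),
                rep("acid phosphatase", 2), "N assimilation",
                "dissimilatory sulfate reduction"),
    taxon = c("Bradyrhizobium", "Mycobacterium",
              "Bradyrhizobium", "Mycobacterium", "Bacillus", "Bacillus"),
    weight = c(5, 3, 4, 2, 6, 2), stringsAsFactors = FALSE)
}

test_that("bipartite construction filters by weight and drops unassigned taxa", {
  counts <- data.frame(pathway = c("A", "A", "B", "B"),
                       taxon = c("G1", "G2", "G1", "UNASSIGNED"),
                       weight = c(5, 1, 2, 50), stringsAsFactors = FALSE)
  g <- build_bipartite(counts, min_weight = 2)
  expect_setequal(igraph::V(g)$name, c("A", "B", "G1"))
  expect_equal(igraph::ecount(g), 2)
  w <- setNames(igraph::E(g)$weight, attr(igraph::E(g), "vnames"))
  expect_equal(unname(w["A|G1"]), 5)
  expect_equal(unname(w["B|G1"]), 2)
  expect_true(igraph::is_bipartite(g))

  g_all <- build_bipartite(counts, min_weight = 1)
  expect_equal(igraph::ecount(g_all), 3) # UNASSIGNED still never an edge
  expect_false("UNASSIGNED" %in% igraph::V(g_all)$name)

  g_bin <- build_bipartite(counts, min_weight = 2, binary = TRUE)
  expect_true(all(igraph::E(g_bin)$weight == 1))

  expect_error(build_bipartite(counts, min_weight = 100), "no edges")
})

test_that("module subnetworks keep only within-module edges", {
  counts <- data.frame(pathway = c("A", "A", "B"),
                       taxon = c("G1", "G2", "G2"),
                       weight = c(3, 1, 4), stringsAsFactors = FALSE)
  g <- build_bipartite(counts)
  part <- c(A = 0, G1 = 0, B = 1, G2 = 1)
  subs <- induce_subnetworks(g, part)
  expect_named(subs, c("0", "1"))
  expect_setequal(igraph::V(subs[["0"]])$name, c("A", "G1"))
  expect_equal(igraph::ecount(subs[["0"]]), 1)          # A-G2 edge excluded
  expect_setequal(igraph::V(subs[["1"]])$name, c("B", "G2"))
  # union of subnetwork edges is a subset of g's edges; cross edges absent
  sub_edges <- unlist(lapply(subs, function(s)
    attr(igraph::E(s), "vnames")))
  expect_true(all(sub_edges %in% attr(igraph::E(g), "vnames")))
  expect_false("A|G2" %in% sub_edges)
})

test_that("couplings pair the cycles present in a module with shared taxa as drivers", {
  cat <- toy_catalog()
  g <- build_bipartite(toy_counts(), cat = cat)
  # module 0: methane oxidation (C) + acid phosphatase (P) + two taxa
  # module 1: N assimilation (N) + sulfate reduction (S) + Bacillus
  part <- c("aerobic methane oxidation" = 0, "acid phosphatase" = 0,
            Bradyrhizobium = 0, Mycobacterium = 0,
            "N assimilation" = 1, "dissimilatory sulfate reduction" = 1,
            Bacillus = 1)
  rep <- detect_couplings(part, g, cat)
  expect_equal(nrow(rep$couplings), 2)
  cp <- rep$couplings[rep$couplings$module == 0, ]
  expect_equal(c(cp$cycle_a, cp$cycle_b), c("C", "P"))
  expect_setequal(rep$driver_sets[["0:C-P"]],
                  c("Bradyrhizobium", "Mycobacterium"))
  expect_setequal(rep$driver_sets[["1:N-S"]], "Bacillus")

  # node ordering does not matter
  rep2 <- detect_couplings(part[rev(seq_along(part))], g, cat)
  expect_equal(rep2$couplings, rep$couplings)

  # a module whose functions share one cycle yields no couplings
  part_mono <- part
  part_mono[c("acid phosphatase")] <- 2
  rep3 <- detect_couplings(part_mono, g, cat)
  expect_false(0 %in% rep3$couplings$module &
                 "P" %in% rep3$couplings$cycle_b[rep3$couplings$module == 0])

  # four cycles in one module: choose(4, 2) pairs
  part_all <- setNames(rep(0, length(part)), names(part))
  rep4 <- detect_couplings(part_all, g, cat)
  expect_equal(nrow(rep4$couplings), choose(4, 2))

  # unknown pathway is an error
  cat_small <- make_catalog(data.frame(
    pathway = "acid phosphatase", cycle = "P", marker_id = "PF03767",
    db = "Pfam", stringsAsFactors = FALSE))
  expect_error(detect_couplings(part, g, cat_small), "not in catalog")
})

test_that("driver taxa must touch both cycles of the pair within the module", {
  cat <- toy_catalog()
  counts <- data.frame(
    pathway = c("aerobic methane oxidation", "acid phosphatase",
                "acid phosphatase"),
    taxon = c("Bradyrhizobium", "Bradyrhizobium", "Nocardia"),
    weight = c(2, 3, 4), stringsAsFactors = FALSE)
  g <- build_bipartite(counts, cat = cat)
  part <- setNames(rep(0, 4), c("aerobic methane oxidation",
                                "acid phosphatase", "Bradyrhizobium",
                                "Nocardia"))
  rep <- detect_couplings(part, g, cat)
  # Nocardia only touches the P side, so it is not a C-P driver
  expect_equal(rep$driver_sets[["0:C-P"]], "Bradyrhizobium")
})

test_that("network export round-trips through GraphML and the edge list", {
  cat <- toy_catalog()
  g <- build_bipartite(toy_counts(), cat = cat)
  part <- cluster_modules(g, seed = 0)
  stem <- file.path(withr::local_tempdir(), "net")
  files <- export_network(g, part, stem)
  expect_true(all(file.exists(files)))

  g2 <- igraph::read_graph(files[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  # weights and module attributes survive
  m2 <- setNames(igraph::V(g2)$module, igraph::V(g2)$name)
  expect_equal(m2[names(part$membership)], part$membership,
               ignore_attr = TRUE)
  w2 <- sort(igraph::E(g2)$weight)
  expect_equal(w2, sort(igraph::E(g)$weight))

  el <- read.delim(files[["edges"]], check.names = FALSE)
  expect_equal(nrow(el), igraph::ecount(g))
  expect_named(el, c("function", "taxon", "weight", "module_function",
                     "module_taxon"))
  expect_true(all(el$module_function ==
                    part$membership[el$`function`]))
})
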