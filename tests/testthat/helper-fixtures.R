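# shared fixtures and independent oracles

# write a contig annotation TSV from row strings and read it back
contig_header <- paste(c("contig_id", "sample_id", "length_bp", "marker_ids",
                         "kingdom", "phylum", "class", "order", "family",
                         "genus"), collapse = "\t")

contig_tsv <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(c(contig_header, rows), f)
  f
}

# row builder: lineage filled down to `depth` ranks with given names
crow <- function(contig, sample, len, markers, ...) {
  lineage <- rep("", 6)
  ranks <- c(...)
  lineage[seq_along(ranks)] <- ranks
  paste(c(contig, sample, len, markers, lineage), collapse = "\t")
}

# catalog from a data frame, via the public TSV loader (stand-alone)
make_catalog <- function(df) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  if (is.null(df$gene_symbol)) df$gene_symbol <- ""
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  load_catalog(f, base = NULL)
}

# small weighted graph from an edge data frame (from, to, weight)
make_graph <- function(edges) {
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

# --- independent modularity oracle: naive double loop over node pairs ---
oracle_modularity <- function(A, mem, gamma = 1) {
  two_w <- sum(A)
  if (two_w == 0) return(0)
  k <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mem[i] == mem[j]) q <- q + A[i, j] - gamma * k[i] * k[j] / two_w
    }
  }
  q / two_w
}

# enumerate all set partitions of n items as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxl) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) rec(c(prefix, l), max(maxl, l))
  }
  rec(integer(), 0L)
  out
}

# exhaustive best modularity over all partitions (oracle formula)
oracle_best_partition <- function(A, gamma = 1) {
  parts <- all_partitions(nrow(A))
  qs <- vapply(parts, function(p) oracle_modularity(A, p, gamma), numeric(1))
  best <- which.max(qs)
  list(q = qs[best], membership = parts[[best]])
}

adjacency_of <- function(g) {
  attr <- if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL
  igraph::as_adjacency_matrix(g, attr = attr, sparse = FALSE)
}

# a battery of small graphs (<= 8 nodes) for exhaustive-oracle checks
small_test_graphs <- function() {
  list(
    single_edge = make_graph(data.frame(from = "a", to = "b", weight = 1)),
    two_disjoint_edges = make_graph(
      data.frame(from = c("a", "c"), to = c("b", "d"), weight = 1)),
    path6 = make_graph(
      data.frame(from = letters[1:5], to = letters[2:6], weight = 1)),
    two_stars = make_graph(
      data.frame(from = c("h1", "h1", "h2", "h2"),
                 to = c("l1", "l2", "l3", "l4"), weight = 1)),
    k23 = make_graph(
      data.frame(from = rep(c("f1", "f2"), each = 3),
                 to = rep(c("t1", "t2", "t3"), 2), weight = 1)),
    weighted_blocks = make_graph(
      data.frame(from = c("f1", "f1", "f2", "f2", "f3", "f1"),
                 to = c("t1", "t2", "t1", "t2", "t3", "t3"),
                 weight = c(5, 4, 3, 6, 7, 0.5)))
  )
}

# planted cycle-pair sets per module, from the generator's ground truth
planted_cycle_pairs <- function(truth) {
  lapply(split(names(truth$fn_module), truth$fn_module), function(fns) {
    cyc <- sort(unique(unname(truth$cycles[fns])))
    if (length(cyc) < 2) return(character())
    apply(utils::combn(cyc, 2), 2, paste, collapse = "-")
  })
}
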