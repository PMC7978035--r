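#' Weighted modularity with a resolution parameter
#'
#' Newman modularity of a partition of a weighted undirected graph,
#' Q = (1/2W) * sum_ij \[A_ij - gamma * k_i k_j / (2W)\] * delta(c_i, c_j),
#' with W the total edge weight and k the weighted degrees. The resolution
#' gamma rescales the null-model term; gamma = 1 is standard modularity. A
#' bipartite graph is scored as an ordinary undirected weighted graph (the
#' convention of general-purpose network tools), not with a bipartite-
#' specific null model.
#'
#' @param g An [igraph][igraph::igraph-package] graph (edge attribute
#'   `weight` used if present, else unit weights).
#' @param membership Module assignment: named vector covering every vertex
#'   (names = vertex names), or an unnamed vector in vertex order.
#' @param gamma Resolution parameter (default 1).
#' @return Q, a single number.
#' @export
modularity_score <- function(g, membership, gamma = 1) {
  A <- graph_adjacency(g)
  mem <- resolve_membership(membership, rownames(A))
  modularity_from_adjacency(A, mem, gamma)
}

graph_adjacency <- function(g) {
  attr <- if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL
  igraph::as_adjacency_matrix(g, attr = attr, sparse = FALSE)
}

resolve_membership <- function(membership, node_names) {
  if (!is.null(names(membership))) {
    missing_nodes <- setdiff(node_names, names(membership))
    if (length(missing_nodes) > 0)
      stopf("membership lacks node(s): %s",
            paste(missing_nodes, collapse = ", "))
    membership <- membership[node_names]
  } else if (length(membership) != length(node_names)) {
    stopf("membership length %d does not match %d vertices",
          length(membership), length(node_names))
  }
  as.integer(factor(membership))
}

# core formula on a dense adjacency; diagonal entries (self-loops from
# aggregation) contribute A_ii and k includes them once
modularity_from_adjacency <- function(A, mem, gamma) {
  two_w <- sum(A)
  if (two_w == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (c in unique(mem)) {
    idx <- mem == c
    q <- q + sum(A[idx, idx]) - gamma * sum(k[idx])^2 / two_w
  }
  q / two_w
}

# One Louvain level: repeated local moves over `ord` until no move improves
# Q. Ties in gain are broken toward the lowest community id. `init` seeds
# the starting assignment (labels in 1..n), enabling refinement passes.
louvain_local_moves <- function(A, gamma, ord, init = seq_len(nrow(A))) {
  n <- nrow(A)
  comm <- init
  k <- rowSums(A)
  two_w <- sum(A)
  sigma_tot <- numeric(n) # per-community degree sums, indexed by label
  for (i in seq_len(n)) sigma_tot[comm[i]] <- sigma_tot[comm[i]] + k[i]
  eps <- 1e-12
  repeat {
    moved <- FALSE
    for (i in ord) {
      ci <- comm[i]
      w_i <- A[i, ]
      sigma_tot[ci] <- sigma_tot[ci] - k[i]
      # weight from i to each candidate community (neighbours + current)
      nb <- which(w_i > 0 & seq_len(n) != i)
      cand <- sort(unique(c(ci, comm[nb])))
      links <- vapply(cand, function(cc) sum(w_i[comm == cc & seq_len(n) != i]),
                      numeric(1))
      gain <- links / two_w * 2 - 2 * gamma * k[i] * sigma_tot[cand] / two_w^2
      best <- cand[which.max(gain)] # which.max takes the first (lowest id)
      cur <- gain[match(ci, cand)]
      if (gain[match(best, cand)] > cur + eps && best != ci) {
        comm[i] <- best
        moved <- TRUE
      }
      sigma_tot[comm[i]] <- sigma_tot[comm[i]] + k[i]
    }
    if (!moved) break
  }
  comm
}

louvain_aggregate <- function(A, comm) {
  f <- factor(comm)
  M <- outer(levels(f), levels(f), Vectorize(function(a, b) {
    sum(A[f == a, f == b, drop = FALSE])
  }))
  M
}

# Iterated multilevel scheme: alternate local moves at the original node
# level (refining the current partition) with moves on the aggregated
# community graph (merging whole communities), until Q stops improving.
# The refinement pass lets individual nodes escape communities frozen by
# early aggregation, a known weakness of plain single-sweep Louvain.
louvain_run <- function(A, gamma, seed) {
  n <- nrow(A)
  mem <- seq_len(n)
  q <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    ord <- with_seed(seed + it * 101L, sample.int(n))
    mem <- as.integer(factor(louvain_local_moves(A, gamma, ord, init = mem)))
    if (max(mem) > 1L) {
      B <- louvain_aggregate(A, mem)
      ord_b <- with_seed(seed + it * 101L + 57L, sample.int(nrow(B)))
      mem_b <- as.integer(factor(louvain_local_moves(B, gamma, ord_b)))
      mem <- mem_b[mem]
    }
    q_new <- modularity_from_adjacency(A, mem, gamma)
    if (q_new <= q + 1e-12 || it >= 50L) break
    q <- q_new
  }
  mem
}

# exact maximum-modularity partition by enumeration of all set
# partitions (restricted-growth strings); feasible up to ~8 nodes
exact_best_partition <- function(A, gamma) {
  n <- nrow(A)
  best_q <- -Inf
  best <- rep(1L, n)
  rec <- function(prefix, maxl) {
    if (length(prefix) == n) {
      q <- modularity_from_adjacency(A, prefix, gamma)
      if (q > best_q + 1e-15) {
        best_q <<- q
        best <<- prefix
      }
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) rec(c(prefix, l), max(maxl, l))
  }
  rec(integer(), 0L)
  best
}

#' Cluster a graph by modularity maximisation
#'
#' Maximises [modularity_score()]'s objective. Graphs with at most
#' `exact_max` nodes are solved exactly by enumerating every set partition
#' (Bell(8) = 4140 candidates, instantaneous); larger graphs use a
#' Louvain-style multilevel heuristic: repeated single-node moves (in a
#' seed-shuffled visit order, ties broken toward the lowest module id),
#' graph aggregation, and refinement passes back at the original node
#' level, iterated until Q stops improving, over several restarts with
#' derived seeds, keeping the highest-Q partition. On the strongly modular
#' graphs typical of function-taxon networks this reliably reaches the
#' global optimum. Module ids are renumbered 0, 1, ... by decreasing
#' module size (ties by first member) for stable reporting.
#'
#' @inheritParams modularity_score
#' @param gamma Resolution (default 1, the conventional setting).
#' @param seed RNG seed controlling visit order; results are reproducible
#'   for a fixed seed.
#' @param n_restarts Number of heuristic restarts (default 5).
#' @param exact_max Largest node count solved by exact enumeration
#'   (default 8).
#' @return A `module_partition`: list with `membership` (named integer
#'   vector, 0-based module ids), `Q`, `gamma`, `seed`, `n_modules`.
#' @export
cluster_modules <- function(g, gamma = 1, seed = 0, n_restarts = 5,
                            exact_max = 8) {
  A <- graph_adjacency(g)
  if (nrow(A) == 0) stopf("cluster_modules: empty graph")
  if (nrow(A) <= exact_max) {
    best <- exact_best_partition(A, gamma)
    best_q <- modularity_from_adjacency(A, best, gamma)
  } else {
    best <- NULL
    best_q <- -Inf
    for (r in seq_len(n_restarts)) {
      mem <- louvain_run(A, gamma, seed + (r - 1L))
      q <- modularity_from_adjacency(A, mem, gamma)
      if (q > best_q + 1e-12) {
        best_q <- q
        best <- mem
      }
    }
  }
  # renumber by decreasing size; ties by first appearance
  sizes <- table(best)
  first_seen <- tapply(seq_along(best), best, min)
  ord <- order(-as.integer(sizes), as.integer(first_seen))
  relabel <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  membership <- stats::setNames(unname(relabel[as.character(best)]),
                                rownames(A))
  structure(list(membership = membership, Q = best_q, gamma = gamma,
                 seed = seed, n_modules = length(unique(membership))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules over %d nodes, Q = %.4f (gamma = %g, seed = %d)\n",
              x$n_modules, length(x$membership), x$Q, x$gamma, x$seed))
  print(table(module = x$membership))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes
#' (via [mclust::adjustedRandIndex()]); 1 means identical partitions, 0 is
#' the expectation for independent ones. Used to score recovery of planted
#' modules.
#'
#' @param a,b Two membership vectors; if named, aligned by name.
#' @return The adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stopf("adjusted_rand: partitions cover different node sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stopf("adjusted_rand: partitions have different lengths")
  }
  mclust::adjustedRandIndex(a, b)
}
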