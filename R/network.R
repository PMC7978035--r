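#' Build the function-taxon bipartite graph
#'
#' Turns a [function_taxon_counts()] table into a weighted undirected
#' bipartite graph: function (pathway) nodes on one side, taxon nodes on
#' the other, an edge for each (pathway, taxon) pair whose pooled contig
#' count reaches `min_weight`. Unassigned taxa never enter the graph, and
#' nodes left without edges after filtering are dropped. With
#' `binary = TRUE` all surviving edge weights are set to 1 (presence/
#' absence weighting).
#'
#' @param ftc A `function_taxon_counts` object (or a data frame with
#'   columns `pathway`, `taxon`, `weight`).
#' @param min_weight Minimum contig count for an edge (default 1, i.e. no
#'   filtering).
#' @param binary If `TRUE`, ignore counts and use unit weights.
#' @param cat Optional `marker_catalog` used to attach a `cycle` attribute
#'   to function nodes.
#' @return An igraph graph with vertex attributes `name`, `kind`
#'   (`"function"`/`"taxon"`), `type` (logical, igraph bipartite
#'   convention: taxon = TRUE) and optionally `cycle`; edge attribute
#'   `weight`.
#' @export
build_bipartite <- function(ftc, min_weight = 1, binary = FALSE, cat = NULL) {
  counts <- if (inherits(ftc, "function_taxon_counts")) ftc$counts else ftc
  if (min_weight < 1) stopf("build_bipartite: min_weight must be >= 1")
  keep <- counts$weight >= min_weight & counts$taxon != UNASSIGNED
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0)
    stopf("build_bipartite: no edges survive min_weight = %g", min_weight)
  fn <- unique(counts$pathway)
  tx <- unique(counts$taxon)
  clash <- intersect(fn, tx)
  if (length(clash) > 0)
    stopf("build_bipartite: label(s) used both as pathway and taxon: %s",
          paste(clash, collapse = ", "))
  edges <- data.frame(from = counts$pathway, to = counts$taxon,
                      weight = if (binary) 1 else counts$weight,
                      stringsAsFactors = FALSE)
  vertices <- data.frame(name = c(fn, tx),
                         kind = rep(c("function", "taxon"),
                                    c(length(fn), length(tx))),
                         type = rep(c(FALSE, TRUE),
                                    c(length(fn), length(tx))),
                         stringsAsFactors = FALSE)
  if (!is.null(cat)) {
    cyc <- pathway_cycle_map(cat)
    vertices$cycle <- ifelse(vertices$kind == "function",
                             unname(cyc[normalize_pathway(vertices$name)]),
                             NA_character_)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

partition_membership <- function(part) {
  if (inherits(part, "module_partition")) part$membership else part
}

#' Induce one subnetwork per module
#'
#' For each module of a partition, the subgraph of the bipartite network on
#' that module's function and taxon nodes, keeping only edges whose two
#' endpoints are both members. Edges across modules are excluded by
#' construction.
#'
#' @param g Bipartite graph from [build_bipartite()].
#' @param part A `module_partition` (or named membership vector).
#' @return Named list of igraph subgraphs, one per module id.
#' @export
induce_subnetworks <- function(g, part) {
  mem <- partition_membership(part)
  nodes <- igraph::V(g)$name
  missing_nodes <- setdiff(nodes, names(mem))
  if (length(missing_nodes) > 0)
    stopf("partition lacks node(s): %s", paste(missing_nodes, collapse = ", "))
  mods <- sort(unique(mem[nodes]))
  out <- lapply(mods, function(m) {
    igraph::induced_subgraph(g, nodes[mem[nodes] == m])
  })
  stats::setNames(out, as.character(mods))
}

#' Detect biogeochemical cycle couplings from network modules
#'
#' A module couples two element cycles when it contains function nodes of
#' both. For every module, the member pathways are grouped by cycle (cycle
#' looked up in the catalog; an unknown pathway is an error), all unordered
#' pairs of represented cycles are reported as couplings, and for each
#' coupling the candidate driver taxa are the taxon nodes of the module
#' adjacent — within the module's induced subgraph — to at least one
#' function of each of the two cycles. The result is deterministic given
#' the partition, graph and catalog, and independent of node order.
#'
#' @param part A `module_partition` (or named membership vector).
#' @param g Bipartite graph from [build_bipartite()].
#' @param cat A `marker_catalog` covering every function node.
#' @return A `coupling_report`: list with `modules` (per-module summary
#'   data frame), `couplings` (data frame: module, cycle_a, cycle_b,
#'   n_drivers, drivers as comma-joined string) and `driver_sets` (list of
#'   character vectors keyed "module:cycle_a-cycle_b").
#' @export
detect_couplings <- function(part, g, cat) {
  mem <- partition_membership(part)
  cyc_map <- pathway_cycle_map(cat)
  subs <- induce_subnetworks(g, part)
  kind <- stats::setNames(igraph::V(g)$kind, igraph::V(g)$name)
  mod_rows <- list()
  cpl_rows <- list()
  driver_sets <- list()
  for (m in names(subs)) {
    sg <- subs[[m]]
    vn <- igraph::V(sg)$name
    fn <- sort(vn[kind[vn] == "function"])
    tx <- sort(vn[kind[vn] == "taxon"])
    cyc <- cyc_map[normalize_pathway(fn)]
    if (anyNA(cyc))
      stopf("detect_couplings: pathway(s) not in catalog: %s",
            paste(fn[is.na(cyc)], collapse = ", "))
    cycles <- sort(unique(unname(cyc)))
    mod_rows[[m]] <- data.frame(
      module = as.integer(m), n_functions = length(fn), n_taxa = length(tx),
      cycles = paste(cycles, collapse = ","),
      functions = paste(fn, collapse = ","), stringsAsFactors = FALSE)
    if (length(cycles) >= 2 && length(fn) > 0) {
      # taxa adjacent (within the module) to >= 1 function of each cycle
      adj_cycles <- lapply(tx, function(t) {
        nb <- igraph::neighbors(sg, t)$name
        unique(unname(cyc[normalize_pathway(nb[kind[nb] == "function"])]))
      })
      names(adj_cycles) <- tx
      pairs <- utils::combn(cycles, 2)
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; b <- pairs[2, k]
        drv <- tx[vapply(adj_cycles,
                         function(cs) a %in% cs && b %in% cs, logical(1))]
        key <- sprintf("%s:%s-%s", m, a, b)
        driver_sets[[key]] <- drv
        cpl_rows[[key]] <- data.frame(
          module = as.integer(m), cycle_a = a, cycle_b = b,
          n_drivers = length(drv), drivers = paste(drv, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  couplings <- if (length(cpl_rows) > 0) do.call(rbind, cpl_rows) else
    data.frame(module = integer(), cycle_a = character(),
               cycle_b = character(), n_drivers = integer(),
               drivers = character(), stringsAsFactors = FALSE)
  rownames(couplings) <- NULL
  modules <- do.call(rbind, mod_rows)
  rownames(modules) <- NULL
  structure(list(modules = modules, couplings = couplings,
                 driver_sets = driver_sets),
            class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat(sprintf("coupling_report: %d modules, %d cycle couplings\n",
              nrow(x$modules), nrow(x$couplings)))
  if (nrow(x$couplings) > 0)
    print(x$couplings[, c("module", "cycle_a", "cycle_b", "n_drivers")])
  invisible(x)
}

#' Export the network as GraphML and an edge-list TSV
#'
#' Writes `<path>.graphml` (node attributes `kind`, `cycle` if present and
#' `module`; edge weights) and `<path>_edges.tsv` with columns `function`,
#' `taxon`, `weight`, `module_function`, `module_taxon`.
#'
#' @param g Bipartite graph.
#' @param part A `module_partition` (or named membership vector).
#' @param path Output path stem (extensions are appended).
#' @return Invisibly, the two file paths.
#' @export
export_network <- function(g, part, path) {
  mem <- partition_membership(part)
  nodes <- igraph::V(g)$name
  missing_nodes <- setdiff(nodes, names(mem))
  if (length(missing_nodes) > 0)
    stopf("partition lacks node(s): %s", paste(missing_nodes, collapse = ", "))
  g <- igraph::set_vertex_attr(g, "module", value = as.integer(mem[nodes]))
  graphml <- paste0(path, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  kind <- stats::setNames(igraph::V(g)$kind, nodes)
  # orient each edge function -> taxon
  flip <- kind[el$from] == "taxon"
  fn <- ifelse(flip, el$to, el$from)
  tx <- ifelse(flip, el$from, el$to)
  tsv <- paste0(path, "_edges.tsv")
  out <- data.frame(`function` = fn, taxon = tx, weight = el$weight,
                    module_function = as.integer(mem[fn]),
                    module_taxon = as.integer(mem[tx]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml = graphml, edges = tsv))
}
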