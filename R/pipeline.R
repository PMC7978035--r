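#' Pipeline run configuration
#'
#' Validates and freezes everything [run_full_pipeline()] needs. Exactly
#' one input mode must be chosen: file paths (`contigs` + `metadata`, with
#' an optional `catalog` TSV merged over the built-in) or a
#' [synthetic_config()].
#'
#' @param contigs,metadata,catalog Input TSV paths (file mode).
#' @param synthetic A [synthetic_config()] (synthetic mode).
#' @param rank Taxonomic rank for taxon aggregation (default `"genus"`).
#' @param min_weight Minimum contig count for a network edge (default 1).
#' @param resolution Modularity resolution gamma (default 1).
#' @param n_perm Permutations for MRM / distance-decay (default 999).
#' @param min_contig_length Minimum contig length in bp (default 500).
#' @param seed Master seed (required; all stage seeds derive from it).
#' @param out_dir Output directory (created if absent).
#' @return A `run_config` list.
#' @export
run_config <- function(contigs = NULL, metadata = NULL, catalog = NULL,
                       synthetic = NULL, rank = "genus", min_weight = 1,
                       resolution = 1, n_perm = 999,
                       min_contig_length = 500, seed, out_dir) {
  if (missing(seed)) stopf("run_config: seed is required")
  file_mode <- !is.null(contigs) || !is.null(metadata) || !is.null(catalog)
  if (file_mode && !is.null(synthetic))
    stopf("run_config: provide input paths or a synthetic config, not both")
  if (!file_mode && is.null(synthetic))
    stopf("run_config: provide input paths or a synthetic config")
  if (file_mode && (is.null(contigs) || is.null(metadata)))
    stopf("run_config: file mode needs both contigs and metadata paths")
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  structure(list(contigs = contigs, metadata = metadata, catalog = catalog,
                 synthetic = synthetic, rank = rank, min_weight = min_weight,
                 resolution = resolution, n_perm = n_perm,
                 min_contig_length = min_contig_length,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(stats::setNames(list(rownames(x)), rownames_as),
                    as.data.frame(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the chain profile -> gradient statistics -> network ->
#' couplings and writes every result table under `cfg$out_dir`: abundance
#' matrices (counts, proportions, pooled proportions), taxon assignment
#' rates, diversity table with latitude correlations, PCoA coordinates,
#' MRM and distance-decay results (JSON), latitude trend table, Spearman
#' gene-environment matrices, the GraphML network with its edge list,
#' module membership, and the coupling report (TSV + JSON). Stage timings
#' and record counts go to `run.log` (the only output that is not
#' byte-reproducible across runs); every data output is identical for an
#' identical configuration and seed.
#'
#' @param cfg A [run_config()].
#' @param verbose Print stage progress to stderr (default TRUE).
#' @return A `run_report`: list with `paths` (named output files),
#'   `summary` (key figures: sample/contig/module/coupling counts,
#'   modularity Q, distance-decay slope, MRM R^2) and the main in-memory
#'   objects (`partition`, `couplings`, `trends`, ...).
#' @export
run_full_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  t0 <- Sys.time()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    if (verbose) message(msg)
    log_lines <<- c(log_lines, sprintf("[%6.2fs] %s",
                                       as.numeric(Sys.time() - t0, "secs"),
                                       msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  paths <- list()
  out <- function(f) file.path(cfg$out_dir, f)

  # ---- inputs ----
  if (!is.null(cfg$synthetic)) {
    say("stage input: simulating synthetic transect (seed %d)", cfg$synthetic$seed)
    meta <- stage("input", simulate_metadata(cfg$synthetic))
    sim <- stage("input", simulate_contigs(cfg$synthetic, meta))
    tab <- sim$annotations
    cat <- sim$catalog
    paths$metadata <- write_tsv(meta, out("metadata.tsv"))
    paths$catalog <- write_catalog(cat, out("catalog.tsv"))
    cfg_echo <- cfg$synthetic
    class(cfg_echo) <- NULL
    paths$config <- write_json_out(
      c(cfg_echo[!vapply(cfg_echo, is.null, logical(1))],
        list(rank = cfg$rank, min_weight = cfg$min_weight,
             resolution = cfg$resolution, n_perm = cfg$n_perm,
             pipeline_seed = cfg$seed)),
      out("config.json"))
  } else {
    say("stage input: reading %s", cfg$contigs)
    tab <- stage("input",
                 read_contig_annotations(cfg$contigs, cfg$min_contig_length))
    meta <- stage("input", read_sample_metadata(cfg$metadata))
    cat <- stage("input",
                 if (is.null(cfg$catalog)) builtin_catalog()
                 else load_catalog(cfg$catalog))
  }
  say("input: %d contigs, %d samples, %d catalog pathways",
      nrow(tab), length(unique(tab$sample_id)), nrow(cat$entries))

  # ---- profiling ----
  say("stage profile")
  counts <- stage("profile", marker_count_matrix(tab, cat))
  props <- stage("profile", pathway_proportions(tab, cat))
  rates <- stage("profile", assignment_rate(tab, cat, cfg$rank))
  ftc <- stage("profile", function_taxon_counts(tab, cat, cfg$rank))
  # drop never-observed pathways (e.g. built-in placeholders) from stats
  observed <- colnames(counts)[colSums(counts) > 0]
  if (length(observed) < 2)
    stopf("pipeline stage 'profile' failed: fewer than two pathways observed")
  counts_obs <- counts[, observed, drop = FALSE]
  props_obs <- props$per_sample[, observed, drop = FALSE]
  paths$counts <- write_tsv(counts, out("marker_counts.tsv"), "sample_id")
  paths$proportions <- write_tsv(props$per_sample, out("pathway_proportions.tsv"),
                                 "sample_id")
  paths$pooled <- write_tsv(
    data.frame(pathway = names(props$pooled),
               pooled_proportion = unname(props$pooled),
               percent_of_contigs = 100 * unname(props$pooled)),
    out("pooled_proportions.tsv"))
  paths$assignment <- write_tsv(
    data.frame(pathway = names(rates), rank = cfg$rank,
               assignment_rate = unname(rates)),
    out("assignment_rates.tsv"))

  # ---- gradient statistics ----
  say("stage stats: diversity, ordination, MRM (%d permutations)", cfg$n_perm)
  div <- stage("stats", diversity_table(counts_obs, meta))
  paths$diversity <- write_tsv(div$table, out("diversity.tsv"))
  paths$diversity_latitude <- write_tsv(div$latitude_correlation,
                                        out("diversity_latitude.tsv"))
  bc <- stage("stats", bray_curtis(props_obs))
  ord <- stage("stats", pcoa(bc, k = 2))
  paths$pcoa <- write_tsv(ord$coordinates, out("pcoa_coordinates.tsv"),
                          "sample_id")
  geo <- stage("stats", geographic_distance(meta))
  dd <- stage("stats", distance_decay(bc, geo, n_perm = cfg$n_perm,
                                      seed = cfg$seed + 11L))
  paths$distance_decay <- write_json_out(dd, out("distance_decay.json"))
  env_vars <- setdiff(names(meta)[vapply(meta, is.numeric, logical(1))],
                      c("latitude", "longitude"))
  preds <- c(list(geographic_km = geo),
             stats::setNames(lapply(env_vars, function(v)
               variable_distance(meta[[v]], meta$sample_id)), env_vars))
  mrm_res <- stage("stats", mrm(bc, preds, n_perm = cfg$n_perm,
                                seed = cfg$seed + 12L))
  paths$mrm <- write_json_out(unclass(mrm_res), out("mrm.json"))
  trends <- stage("stats", latitude_trends(props_obs, meta))
  paths$trends <- write_tsv(trends, out("latitude_trends.tsv"))
  sp <- stage("stats", spearman_env(props_obs, meta))
  paths$spearman_rho <- write_tsv(sp$rho, out("spearman_rho.tsv"), "pathway")
  paths$spearman_p <- write_tsv(sp$p_value, out("spearman_p.tsv"), "pathway")

  # ---- network ----
  say("stage network: bipartite graph, modularity (gamma = %g)", cfg$resolution)
  g <- stage("network", build_bipartite(ftc, min_weight = cfg$min_weight,
                                        cat = cat))
  part <- stage("network", cluster_modules(g, gamma = cfg$resolution,
                                           seed = cfg$seed))
  say("network: %d nodes, %d edges, %d modules, Q = %.4f",
      igraph::vcount(g), igraph::ecount(g), part$n_modules, part$Q)
  nexp <- stage("network", export_network(g, part, out("network")))
  paths$graphml <- nexp[["graphml"]]
  paths$edges <- nexp[["edges"]]
  paths$modules <- write_tsv(
    data.frame(node = names(part$membership),
               kind = igraph::V(g)$kind[match(names(part$membership),
                                              igraph::V(g)$name)],
               module = unname(part$membership)),
    out("module_membership.tsv"))

  # ---- couplings ----
  say("stage couplings")
  cpl <- stage("couplings", detect_couplings(part, g, cat))
  paths$module_summary <- write_tsv(cpl$modules, out("module_summary.tsv"))
  paths$couplings <- write_tsv(cpl$couplings, out("couplings.tsv"))
  paths$couplings_json <- write_json_out(
    list(modules = cpl$modules, couplings = cpl$couplings),
    out("couplings.json"))

  summary <- list(
    n_samples = length(unique(tab$sample_id)),
    n_contigs = nrow(tab),
    n_pathways_observed = length(observed),
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    n_modules = part$n_modules, modularity_Q = part$Q,
    n_couplings = nrow(cpl$couplings),
    distance_decay_slope = dd$slope, distance_decay_p = dd$p_value,
    mrm_r_squared = mrm_res$r_squared,
    n_trend_significant = sum(trends$significant, na.rm = TRUE))
  say("done: %d modules, %d couplings", summary$n_modules, summary$n_couplings)
  writeLines(log_lines, out("run.log"))
  paths$log <- out("run.log")
  structure(list(paths = paths, summary = summary, config = cfg,
                 partition = part, graph = g, couplings = cpl,
                 trends = trends, mrm = mrm_res, distance_decay = dd,
                 diversity = div, proportions = props),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("biogeonet pipeline report\n")
  s <- x$summary
  cat(sprintf("  %d samples, %d contigs, %d pathways observed\n",
              s$n_samples, s$n_contigs, s$n_pathways_observed))
  cat(sprintf("  network: %d nodes / %d edges -> %d modules (Q = %.4f), %d couplings\n",
              s$n_nodes, s$n_edges, s$n_modules, s$modularity_Q,
              s$n_couplings))
  cat(sprintf("  distance-decay slope %.3g (p = %.4g); MRM R^2 = %.3f\n",
              s$distance_decay_slope, s$distance_decay_p, s$mrm_r_squared))
  cat(sprintf("  outputs in %s\n", x$config$out_dir))
  invisible(x)
}
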