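#' Synthetic transect configuration
#'
#' Parameters of the synthetic-data generator, which emulates the
#' statistical structure the analysis chain assumes: 45 forest-soil
#' samples along an 18-48 degN latitudinal transect, soil pH rising
#' roughly 5 units across it, marker-gene abundances with log-linear
#' latitude trends, and a planted modular function-taxon association
#' structure (8 modules by default, echoing the cluster count typical of
#' such networks).
#'
#' @param n_samples Number of samples (default 45).
#' @param lat_range Latitude range in decimal degrees N (default c(18, 48)).
#' @param ph0 pH at the southern end of the transect (default 4.5).
#' @param ph_beta pH change per degree latitude; default spans ~5 units
#'   over the transect.
#' @param sigma_ph SD of pH noise (default 0.25).
#' @param n_modules Number of planted function-taxon modules K (default 8).
#' @param functions_per_module Pathways per module (default 2).
#' @param taxa_per_module Taxa per module (default 6).
#' @param contigs_per_sample Contigs per sample N_s (default 5000).
#' @param marker_fraction Fraction of contigs carrying a marker (default
#'   0.5; the rest are unannotated background).
#' @param slopes Per-function log-linear latitude slopes b_f (log relative
#'   abundance per degree). Default: one third of functions at
#'   +log(2)/span (doubling across the transect), one third at the
#'   negative, one third flat.
#' @param eps_out Probability that a marker contig's taxon is drawn from
#'   outside its function's module (default 0.05).
#' @param rho_assign Probability that a contig's genus is assigned
#'   (default 0.7; the rest are unassigned at genus).
#' @param seed RNG seed; every downstream draw is derived from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 45, lat_range = c(18, 48),
                             ph0 = 4.5, ph_beta = 5 / diff(lat_range),
                             sigma_ph = 0.25, n_modules = 8,
                             functions_per_module = 2, taxa_per_module = 6,
                             contigs_per_sample = 5000,
                             marker_fraction = 0.5, slopes = NULL,
                             eps_out = 0.05, rho_assign = 0.7, seed = 0) {
  stopifnot(n_samples >= 2, n_modules >= 1, functions_per_module >= 1,
            taxa_per_module >= 1, contigs_per_sample >= 1,
            marker_fraction >= 0, marker_fraction <= 1,
            eps_out >= 0, eps_out <= 1, rho_assign >= 0, rho_assign <= 1,
            diff(lat_range) > 0)
  cfg <- list(n_samples = n_samples, lat_range = lat_range, ph0 = ph0,
              ph_beta = ph_beta, sigma_ph = sigma_ph, n_modules = n_modules,
              functions_per_module = functions_per_module,
              taxa_per_module = taxa_per_module,
              contigs_per_sample = contigs_per_sample,
              marker_fraction = marker_fraction, slopes = slopes,
              eps_out = eps_out, rho_assign = rho_assign,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

# deterministic generator design: functions, cycles, module maps, baseline
# log-abundances a_f and latitude slopes b_f
synthetic_design <- function(cfg) {
  n_fn <- cfg$n_modules * cfg$functions_per_module
  n_tx <- cfg$n_modules * cfg$taxa_per_module
  fn <- sprintf("fn%02d", seq_len(n_fn))
  tx <- sprintf("tax%02d", seq_len(n_tx))
  cycles <- rep_len(CYCLE_CODES, n_fn)
  fn_module <- rep(seq_len(cfg$n_modules), each = cfg$functions_per_module)
  tx_module <- rep(seq_len(cfg$n_modules), each = cfg$taxa_per_module)
  a_f <- with_seed(cfg$seed, stats::runif(n_fn, -0.5, 0.5))
  if (is.null(cfg$slopes)) {
    b2 <- log(2) / diff(cfg$lat_range) # doubling across the transect
    b_f <- rep_len(c(b2, -b2, 0), n_fn)
  } else {
    if (length(cfg$slopes) != n_fn)
      stopf("synthetic_design: slopes length %d != %d functions",
            length(cfg$slopes), n_fn)
    b_f <- cfg$slopes
  }
  list(functions = fn, taxa = tx, cycles = stats::setNames(cycles, fn),
       fn_module = stats::setNames(fn_module, fn),
       tx_module = stats::setNames(tx_module, tx),
       a_f = stats::setNames(a_f, fn), b_f = stats::setNames(b_f, fn))
}

#' Planted ground truth of the generator
#'
#' The module map and latitude slopes the generator actually uses, for
#' recovery scoring (adjusted Rand index against inferred modules; power
#' and type-I checks against planted slopes).
#'
#' @param cfg A [synthetic_config()].
#' @return List with `modules` (named vector over function and taxon
#'   nodes), `fn_module`, `tx_module`, `slopes`, `cycles`, `ph` (model
#'   parameters).
#' @export
planted_truth <- function(cfg) {
  des <- synthetic_design(cfg)
  list(modules = c(des$fn_module, des$tx_module),
       fn_module = des$fn_module, tx_module = des$tx_module,
       slopes = des$b_f, cycles = des$cycles,
       ph = list(ph0 = cfg$ph0, beta = cfg$ph_beta, sigma = cfg$sigma_ph))
}

#' Simulate sample metadata along the transect
#'
#' Sites evenly spread over the latitude range with uniform jitter of
#' +/- 0.3 degrees (clamped to the range), longitudes on a smooth
#' south-west to north-east arc, pH following
#' pH = pH0 + beta * (lat - lat_min) + N(0, sigma_ph), and mean annual
#' temperature / precipitation decreasing with latitude as on a humid
#' east-Asian transect.
#'
#' @param cfg A [synthetic_config()].
#' @return Metadata data frame: `sample_id`, `latitude`, `longitude`,
#'   `pH`, `MAT` (degC), `MAP` (mm), `TOC` (g/kg).
#' @export
simulate_metadata <- function(cfg) {
  n <- cfg$n_samples
  lo <- cfg$lat_range[1]; hi <- cfg$lat_range[2]
  with_seed(cfg$seed + 1L, {
    lat <- seq(lo, hi, length.out = n) + stats::runif(n, -0.3, 0.3)
    lat <- pmin(pmax(lat, lo), hi)
    lon <- 109 + 0.6 * (lat - lo) + stats::rnorm(n, 0, 0.3)
    ph <- cfg$ph0 + cfg$ph_beta * (lat - lo) + stats::rnorm(n, 0, cfg$sigma_ph)
    mat <- 24 - 0.75 * (lat - lo) + stats::rnorm(n, 0, 1)
    map <- 2000 - 45 * (lat - lo) + stats::rnorm(n, 0, 80)
    toc <- exp(stats::rnorm(n, log(25), 0.35))
    data.frame(sample_id = sprintf("S%02d", seq_len(n)),
               latitude = lat, longitude = lon, pH = ph, MAT = mat,
               MAP = map, TOC = toc, stringsAsFactors = FALSE)
  })
}

#' Simulate per-sample marker counts (count level)
#'
#' The count-level core of the generator: per sample, the number of
#' marker-bearing contigs is Binomial(N_s, marker_fraction) and their
#' pathway identities are multinomial with probabilities proportional to
#' exp(a_f + b_f * latitude). A fixed N_s per sample makes proportions
#' directly comparable across samples. This is the fast path used for
#' trend power/type-I studies; [simulate_contigs()] expands it to full
#' contig records.
#'
#' @param cfg A [synthetic_config()].
#' @param meta Metadata from [simulate_metadata()] under the same config.
#' @return List with `counts` (samples x functions integer matrix),
#'   `n_marker` and `n_contigs` (per-sample vectors).
#' @export
simulate_marker_counts <- function(cfg, meta) {
  des <- synthetic_design(cfg)
  n <- nrow(meta)
  with_seed(cfg$seed + 2L, {
    n_marker <- stats::rbinom(n, cfg$contigs_per_sample, cfg$marker_fraction)
    counts <- matrix(0L, n, length(des$functions),
                     dimnames = list(meta$sample_id, des$functions))
    for (i in seq_len(n)) {
      logw <- des$a_f + des$b_f * meta$latitude[i]
      pr <- exp(logw - max(logw))
      counts[i, ] <- stats::rmultinom(1, n_marker[i], pr)[, 1]
    }
    list(counts = counts,
         n_marker = stats::setNames(n_marker, meta$sample_id),
         n_contigs = stats::setNames(rep(cfg$contigs_per_sample, n),
                                     meta$sample_id))
  })
}

#' Simulate a contig annotation table
#'
#' Expands [simulate_marker_counts()] to one record per contig: each
#' marker-bearing contig carries one synthetic marker accession
#' (`SYN#####`, a reserved space that cannot collide with real KO/Pfam
#' ids); its taxon is drawn from its function's planted module with
#' probability 1 - eps_out and uniformly from all taxa otherwise; the
#' genus is reported with probability rho_assign and left unassigned
#' otherwise (higher ranks derive from the taxon's module). The remaining
#' contigs carry no marker and are unassigned below kingdom. Lengths are
#' 500 + Exp(mean 900) bp, truncated to integers.
#'
#' @param cfg A [synthetic_config()].
#' @param meta Metadata from [simulate_metadata()] under the same config.
#' @return List with `annotations` (a `contig_annotations` table) and
#'   `catalog` (the matching synthetic `marker_catalog`).
#' @export
simulate_contigs <- function(cfg, meta) {
  des <- synthetic_design(cfg)
  mc <- simulate_marker_counts(cfg, meta)
  n_fn <- length(des$functions)
  n_tx <- length(des$taxa)
  marker_ids <- sprintf("SYN%05d", seq_len(n_fn))
  cat <- new_marker_catalog(data.frame(
    pathway = des$functions, cycle = unname(des$cycles),
    marker_id = marker_ids, db = "SYN", gene_symbol = des$functions,
    stringsAsFactors = FALSE))
  with_seed(cfg$seed + 3L, {
    # marker contigs, expanded sample-major then function-major
    per_sample_fn <- as.vector(t(mc$counts))       # sample-major blocks
    samp_idx <- rep(rep(seq_len(nrow(meta)), each = n_fn), per_sample_fn)
    fn_idx <- rep(rep.int(seq_len(n_fn), nrow(meta)), per_sample_fn)
    m <- length(fn_idx)
    # taxon: within-module unless an eps_out defection
    mod <- des$fn_module[fn_idx]
    within <- stats::runif(m) >= cfg$eps_out
    tx_idx <- integer(m)
    tpm <- cfg$taxa_per_module
    tx_idx[within] <- (mod[within] - 1L) * tpm +
      sample.int(tpm, sum(within), replace = TRUE)
    tx_idx[!within] <- sample.int(n_tx, sum(!within), replace = TRUE)
    genus_known <- stats::runif(m) < cfg$rho_assign
    taxon <- des$taxa[tx_idx]
    tmod <- des$tx_module[tx_idx]
    mk <- data.frame(
      sample_id = meta$sample_id[samp_idx],
      marker = marker_ids[fn_idx],
      kingdom = "Bacteria",
      phylum = sprintf("Phylum%02d", tmod),
      class = sprintf("Class%02d", tmod),
      order = sprintf("Order%02d", tmod),
      family = sprintf("Family%02d", tmod),
      genus = ifelse(genus_known, taxon, UNASSIGNED),
      stringsAsFactors = FALSE)
    # markerless background contigs
    n_bg <- mc$n_contigs - mc$n_marker
    bg <- data.frame(
      sample_id = rep(meta$sample_id, n_bg), marker = "",
      kingdom = "Bacteria", phylum = UNASSIGNED, class = UNASSIGNED,
      order = UNASSIGNED, family = UNASSIGNED, genus = UNASSIGNED,
      stringsAsFactors = FALSE)
    all_rows <- rbind(mk, bg)
    all_rows <- all_rows[order(all_rows$sample_id), , drop = FALSE]
    n_all <- nrow(all_rows)
    len <- 500L + as.integer(floor(stats::rexp(n_all, 1 / 900)))
    idx_in_sample <- stats::ave(seq_len(n_all), all_rows$sample_id,
                                FUN = seq_along)
    tab <- data.frame(
      contig_id = sprintf("%s_c%05d", all_rows$sample_id, idx_in_sample),
      sample_id = all_rows$sample_id,
      length_bp = len,
      marker_ids = I(lapply(all_rows$marker, function(x)
        if (nzchar(x)) x else character())),
      all_rows[, TAXONOMIC_RANKS],
      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    class(tab) <- c("contig_annotations", "data.frame")
    list(annotations = tab, catalog = cat)
  })
}

#' Simulate a planted-partition bipartite graph
#'
#' Direct graph-level generator for module-recovery benchmarks: K planted
#' modules, each (function, taxon) pair linked with probability `p_in`
#' when the two sides share a module and `p_out` otherwise; unit edge
#' weights. Nodes left isolated are dropped from the graph (the returned
#' truth covers the surviving nodes).
#'
#' @param n_modules K (default 4).
#' @param n_functions Total function nodes (default 16).
#' @param n_taxa Total taxon nodes (default 40).
#' @param p_in Within-module edge probability (default 0.5).
#' @param p_out Between-module edge probability (default 0.02).
#' @param seed RNG seed.
#' @return List with `graph` (igraph) and `truth` (named module vector
#'   over the graph's nodes).
#' @export
simulate_planted_bipartite <- function(n_modules = 4, n_functions = 16,
                                       n_taxa = 40, p_in = 0.5,
                                       p_out = 0.02, seed = 0) {
  stopifnot(n_functions %% n_modules == 0, n_taxa %% n_modules == 0)
  fn <- sprintf("fn%02d", seq_len(n_functions))
  tx <- sprintf("tax%02d", seq_len(n_taxa))
  fn_mod <- rep(seq_len(n_modules), each = n_functions / n_modules)
  tx_mod <- rep(seq_len(n_modules), each = n_taxa / n_modules)
  pr <- ifelse(outer(fn_mod, tx_mod, "=="), p_in, p_out)
  link <- with_seed(seed,
    matrix(stats::runif(length(pr)) < pr, nrow(pr), ncol(pr)))
  idx <- which(link, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("simulate_planted_bipartite: empty graph")
  counts <- data.frame(pathway = fn[idx[, 1]], taxon = tx[idx[, 2]],
                       weight = 1, stringsAsFactors = FALSE)
  g <- build_bipartite(counts, min_weight = 1)
  truth <- c(stats::setNames(fn_mod, fn), stats::setNames(tx_mod, tx))
  list(graph = g, truth = truth[igraph::V(g)$name])
}
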