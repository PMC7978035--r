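#' Read a contig annotation table
#'
#' Reads the per-contig annotation TSV produced upstream (assembly + ORF
#' annotation + taxonomic classification). Expected columns: `contig_id`,
#' `sample_id`, `length_bp`, `marker_ids` (semicolon-separated accessions,
#' possibly empty) and the six ranks `kingdom` through `genus` (empty cell =
#' unassigned). Contigs shorter than `min_length` are dropped with a
#' message; assembly pipelines routinely discard short contigs and 500 bp is
#' the conventional floor. A lineage must be a prefix: once a rank is
#' unassigned every lower rank must be unassigned too.
#'
#' @param path TSV path.
#' @param min_length Minimum contig length in bp (default 500).
#' @return A `contig_annotations` data frame with columns `contig_id`,
#'   `sample_id`, `length_bp`, `marker_ids` (list column of character
#'   vectors) and the six rank columns.
#' @export
read_contig_annotations <- function(path, min_length = 500) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character",
                           na.strings = NULL)
  required <- c("contig_id", "sample_id", "length_bp", "marker_ids",
                TAXONOMIC_RANKS)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stopf("annotation file %s lacks column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  raw <- raw[, required]
  len <- suppressWarnings(as.integer(raw$length_bp))
  bad_len <- is.na(len) | len < 1
  if (any(bad_len))
    stopf("annotation row %d: length_bp '%s' is not a positive integer",
          which(bad_len)[1], raw$length_bp[which(bad_len)[1]])
  raw$length_bp <- len
  for (r in TAXONOMIC_RANKS)
    raw[[r]][!nzchar(raw[[r]])] <- UNASSIGNED
  lin <- as.matrix(raw[, TAXONOMIC_RANKS]) != UNASSIGNED
  # assigned at some rank while unassigned at a higher rank breaks the prefix
  if (ncol(lin) > 1) {
    for (j in 2:ncol(lin)) {
      bad <- lin[, j] & !lin[, j - 1]
      if (any(bad))
        stopf("annotation row %d: rank '%s' assigned but '%s' is not (broken lineage prefix)",
              which(bad)[1], TAXONOMIC_RANKS[j], TAXONOMIC_RANKS[j - 1])
    }
  }
  short <- raw$length_bp < min_length
  if (any(short))
    message(sprintf("read_contig_annotations: dropped %d contig(s) shorter than %d bp",
                    sum(short), min_length))
  raw <- raw[!short, , drop = FALSE]
  raw$marker_ids <- strsplit(raw$marker_ids, ";", fixed = TRUE)
  raw$marker_ids <- lapply(raw$marker_ids, function(x) x[nzchar(x)])
  rownames(raw) <- NULL
  class(raw) <- c("contig_annotations", "data.frame")
  raw
}

#' Write a contig annotation table to TSV
#'
#' Inverse of [read_contig_annotations()] (marker sets re-joined with `;`).
#'
#' @param tab A `contig_annotations` table.
#' @param path Output path.
#' @export
write_contig_annotations <- function(tab, path) {
  out <- as.data.frame(tab)
  out$marker_ids <- vapply(out$marker_ids, paste, character(1), collapse = ";")
  for (r in TAXONOMIC_RANKS) out[[r]][out[[r]] == UNASSIGNED] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# per-contig pathway hits: list of unique pathway labels per contig.
# A contig carrying several markers of one pathway still counts once.
contig_pathways <- function(tab, cat) {
  map <- marker_to_pathway_map(cat)
  lapply(tab$marker_ids, function(ids) unique(unname(map[ids[ids %in% names(map)]])))
}

pathway_levels <- function(cat) cat$entries$pathway

#' Per-sample marker count matrix
#'
#' Cell (sample, pathway) is the number of contigs in that sample carrying
#' at least one of the pathway's marker accessions. A contig annotated with
#' markers of two different pathways counts once for each; multiple markers
#' of the same pathway count once. Placeholder catalog entries
#' (`UNSET:` accessions) are never matched. KO accessions listed in the
#' catalog's replacement map are counted for their Pfam substitute's
#' pathway.
#'
#' @param tab A `contig_annotations` table.
#' @param cat A `marker_catalog`.
#' @return Integer matrix, samples x pathways (all catalog pathways as
#'   columns, in catalog order).
#' @export
marker_count_matrix <- function(tab, cat) {
  samples <- sort(unique(tab$sample_id))
  paths <- pathway_levels(cat)
  m <- matrix(0L, nrow = length(samples), ncol = length(paths),
              dimnames = list(samples, paths))
  hits <- contig_pathways(tab, cat)
  nh <- lengths(hits)
  if (sum(nh) > 0) {
    s <- rep(tab$sample_id, nh)
    p <- unlist(hits, use.names = FALSE)
    tt <- table(factor(s, levels = samples), factor(p, levels = paths))
    m <- m + unclass(tt)
  }
  storage.mode(m) <- "integer"
  m
}

#' Pathway proportions of all contigs
#'
#' Converts marker counts to proportions of *all* contigs in each sample
#' (marker-bearing or not): cell (s, p) = count(s, p) / total contigs in s.
#' Also returns pooled proportions over all samples, pooled(p) =
#' sum_s count(s, p) / sum_s n_contigs(s) — the quantity a statement such as
#' "15.7% of all contigs" refers to. Note the pooled value is not the mean
#' of the per-sample proportions when sample depths differ.
#'
#' @param tab A `contig_annotations` table.
#' @param cat A `marker_catalog`.
#' @return List with `per_sample` (matrix, samples x pathways), `pooled`
#'   (named vector per pathway) and `n_contigs` (named vector per sample).
#' @export
pathway_proportions <- function(tab, cat) {
  counts <- marker_count_matrix(tab, cat)
  n_contigs <- table(factor(tab$sample_id, levels = rownames(counts)))
  n_contigs <- stats::setNames(as.integer(n_contigs), rownames(counts))
  per_sample <- counts / ifelse(n_contigs == 0, NA_real_, n_contigs)
  pooled <- if (sum(n_contigs) > 0) colSums(counts) / sum(n_contigs) else
    stats::setNames(rep(NA_real_, ncol(counts)), colnames(counts))
  list(per_sample = per_sample, pooled = pooled, n_contigs = n_contigs)
}

#' Taxonomic assignment rate per pathway
#'
#' For each pathway, the fraction of its marker-bearing contigs whose
#' lineage is assigned (not `UNASSIGNED`) at the chosen rank, pooled over
#' samples. A pathway with no marker-bearing contigs gets `NA`, not 0.
#'
#' @param tab A `contig_annotations` table.
#' @param cat A `marker_catalog`.
#' @param rank One of kingdom, phylum, class, order, family, genus
#'   (default `"genus"`, the rank at which driver taxa are reported).
#' @return Named numeric vector over catalog pathways, values in \[0, 1\] or
#'   `NA`.
#' @export
assignment_rate <- function(tab, cat, rank = "genus") {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  paths <- pathway_levels(cat)
  hits <- contig_pathways(tab, cat)
  nh <- lengths(hits)
  p <- factor(unlist(hits, use.names = FALSE), levels = paths)
  assigned <- rep(tab[[rank]] != UNASSIGNED, nh)
  tot <- tapply(assigned, p, length, default = 0L)
  yes <- tapply(assigned, p, sum, default = 0L)
  out <- ifelse(tot > 0, yes / tot, NA_real_)
  stats::setNames(as.numeric(out), paths)
}

#' Function-taxon count table
#'
#' Aggregates, pooled over all samples, the number of contigs linking each
#' pathway to each taxon at the chosen rank. Contigs unassigned at that
#' rank are tallied separately per pathway (`$unassigned`) and never enter
#' the network. For every pathway, taxon weights plus the unassigned weight
#' sum to its pooled marker contig count.
#'
#' @inheritParams assignment_rate
#' @return A `function_taxon_counts` object: list with `counts` (data frame
#'   `pathway`, `taxon`, `weight`), `unassigned` (named vector per pathway)
#'   and `rank`.
#' @export
function_taxon_counts <- function(tab, cat, rank = "genus") {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  paths <- pathway_levels(cat)
  hits <- contig_pathways(tab, cat)
  nh <- lengths(hits)
  p <- unlist(hits, use.names = FALSE)
  taxon <- rep(tab[[rank]], nh)
  unassigned <- taxon == UNASSIGNED
  una <- tapply(rep(1L, sum(unassigned)),
                factor(p[unassigned], levels = paths), sum, default = 0L)
  una <- stats::setNames(as.integer(una), paths)
  df <- data.frame(pathway = p[!unassigned], taxon = taxon[!unassigned],
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    agg <- stats::aggregate(list(weight = rep(1L, nrow(df))),
                            by = df[, c("pathway", "taxon")], FUN = sum)
    agg <- agg[order(agg$pathway, agg$taxon), ]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(pathway = character(), taxon = character(),
                      weight = integer(), stringsAsFactors = FALSE)
  }
  structure(list(counts = agg, unassigned = una, rank = rank),
            class = "function_taxon_counts")
}

#' @export
print.function_taxon_counts <- function(x, ...) {
  cat(sprintf("function_taxon_counts at rank '%s': %d (pathway, taxon) pairs, %d pathways, %d taxa\n",
              x$rank, nrow(x$counts), length(unique(x$counts$pathway)),
              length(unique(x$counts$taxon))))
  invisible(x)
}
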