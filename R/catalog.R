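#' Biomarker-gene catalogs
#'
#' A marker catalog maps biogeochemical pathways to the KEGG Orthology (KO,
#' `K#####`) or Pfam (`PF#####`) accessions used as their biomarker genes.
#' Each entry carries the pathway label, its element cycle (one of C, N, P,
#' S, Fe), the accession, the source database and an optional gene symbol.
#' A catalog additionally records KO-to-Pfam replacements: KO markers that
#' were swapped for an equivalent Pfam family because the KO was not
#' recovered in every sample. During profiling a contig annotated with a
#' replaced KO is counted for the pathway of its Pfam substitute.
#'
#' @name marker_catalog
#' @aliases marker_catalog-class
NULL

new_marker_catalog <- function(entries, replacements = character()) {
  entries$pathway <- as.character(entries$pathway)
  entries$cycle <- as.character(entries$cycle)
  entries$marker_id <- as.character(entries$marker_id)
  entries$db <- as.character(entries$db)
  entries$gene_symbol <- as.character(entries$gene_symbol)
  rownames(entries) <- NULL
  structure(list(entries = entries, replacements = replacements),
            class = "marker_catalog")
}

#' @export
print.marker_catalog <- function(x, ...) {
  n_real <- sum(!is_placeholder_id(x$entries$marker_id))
  cat(sprintf("marker_catalog: %d pathways (%d with accessions, %d placeholders), %d KO->Pfam replacements\n",
              nrow(x$entries), n_real, nrow(x$entries) - n_real,
              length(x$replacements)))
  tab <- table(factor(x$entries$cycle, levels = CYCLE_CODES))
  cat("  pathways per cycle:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Built-in biomarker-gene catalog
#'
#' Returns the curated catalog of biomarker genes for C, N, P, S and Fe
#' cycling pathways. Accessions are included for the P-cycle markers (acid
#' phosphatase PF03767, alkaline phosphatase K01077, phytase K01083,
#' oxidative phosphorylation K00937, substrate phosphorylation K08483,
#' polyphosphatase PF00719), the Fe-cycle markers (ferrous oxidation PF00210,
#' ferric reduction PF01794), and the six pathways whose KO markers were
#' replaced by Pfam families (methanogenesis, N2 fixation, ammonification,
#' S oxidation, dissimilatory sulfate reduction, polysulfide reduction); the
#' KO-to-Pfam replacement map is carried in `$replacements`.
#'
#' The remaining pathways are present with their gene symbol only and a
#' placeholder accession of the form `UNSET:<symbol>`. Placeholders are never
#' matched during profiling: their true accessions live in a user-supplied
#' catalog TSV which must be merged in (see [load_catalog()]) before
#' profiling real annotation data. Inventing accessions for them would
#' silently miscount contigs, so the package refuses to guess.
#'
#' @return A `marker_catalog` object: a list with `entries` (data frame with
#'   columns `pathway`, `cycle`, `marker_id`, `db`, `gene_symbol`) and
#'   `replacements` (named character vector, KO accession -> Pfam accession).
#' @examples
#' cat <- builtin_catalog()
#' subset(cat$entries, cycle == "Fe")
#' @export
builtin_catalog <- function() {
  e <- function(pathway, cycle, marker_id, db, gene_symbol = NA_character_) {
    data.frame(pathway = pathway, cycle = cycle, marker_id = marker_id,
               db = db, gene_symbol = gene_symbol, stringsAsFactors = FALSE)
  }
  ph <- function(pathway, cycle, gene_symbol = NA_character_) {
    id <- if (is.na(gene_symbol)) {
      paste0("UNSET:", gsub(" ", "_", normalize_pathway(pathway)))
    } else paste0("UNSET:", gene_symbol)
    e(pathway, cycle, id, NA_character_, gene_symbol)
  }
  entries <- rbind(
    # C cycle
    ph("CO oxidation", "C", "coxL"),
    ph("fermentation", "C", "LDH"),
    ph("anaerobic C fixation", "C", "KorB"),
    ph("aerobic C fixation", "C", "PRK"),
    ph("aerobic methane oxidation", "C"),
    e("methanogenesis", "C", "PF06253", "Pfam"),
    # N cycle
    ph("N assimilation", "N", "glnA"),
    ph("anammox", "N", "ccoN"),
    ph("nitrite oxidation", "N", "narG"),
    ph("denitrification", "N", "norB"),
    ph("nitrate reduction", "N", "modA"),
    ph("N mineralization", "N", "GDH2"),
    ph("nitrification", "N"),
    e("N2 fixation", "N", "PF00142", "Pfam"),
    e("ammonification", "N", "PF01077", "Pfam"),
    # P cycle
    e("acid phosphatase", "P", "PF03767", "Pfam"),
    e("alkaline phosphatase", "P", "K01077", "KEGG"),
    e("phytase", "P", "K01083", "KEGG"),
    e("oxidative phosphorylation", "P", "K00937", "KEGG", "ppk"),
    e("substrate phosphorylation", "P", "K08483", "KEGG", "PtsI"),
    e("polyphosphatase", "P", "PF00719", "Pfam"),
    # S cycle
    ph("S mineralization", "S", "sseA"),
    ph("assimilatory sulfate reduction", "S"),
    e("S oxidation", "S", "PF08770", "Pfam"),
    e("dissimilatory sulfate reduction", "S", "PF13187", "Pfam", "Fer4"),
    e("polysulfide reduction", "S", "PF14589", "Pfam", "NrfD"),
    # Fe cycle
    e("ferrous oxidation", "Fe", "PF00210", "Pfam", "Ferritin"),
    e("ferric reduction", "Fe", "PF01794", "Pfam")
  )
  replacements <- c(
    K14084 = "PF06253",  # methanogenesis
    K02588 = "PF00142",  # N2 fixation
    K05904 = "PF01077",  # ammonification
    K17227 = "PF08770",  # S oxidation
    K00394 = "PF13187",  # dissimilatory sulfate reduction
    K08352 = "PF14589"   # polysulfide reduction
  )
  new_marker_catalog(entries, replacements)
}

catalog_columns <- c("pathway", "cycle", "marker_id", "db", "gene_symbol")

#' Load a biomarker catalog from a TSV file
#'
#' Reads a tab-separated catalog with header columns `pathway`, `cycle`,
#' `marker_id`, `db`, `gene_symbol` (lines starting with `#` are comments)
#' and merges it over [builtin_catalog()]: a file row replaces the built-in
#' entry for the same pathway (matched case-insensitively after whitespace
#' normalisation), so a user catalog supplies the accessions the built-in
#' carries only as placeholders. Rows are validated on load; a malformed
#' accession, an unknown cycle code or a duplicated (pathway, marker_id)
#' pair is rejected with its row number.
#'
#' @param path Path to the catalog TSV.
#' @param base Catalog to merge over; default [builtin_catalog()]. Use
#'   `NULL` to load the file stand-alone.
#' @return A validated `marker_catalog`.
#' @export
load_catalog <- function(path, base = builtin_catalog()) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(setdiff(catalog_columns, "gene_symbol"), names(raw))
  if (length(missing_cols) > 0)
    stopf("catalog file %s lacks column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  if (!"gene_symbol" %in% names(raw)) raw$gene_symbol <- NA_character_
  raw <- raw[, catalog_columns]
  raw$db[is.na(raw$db) | !nzchar(raw$db)] <- NA_character_
  raw$gene_symbol[is.na(raw$gene_symbol) | !nzchar(raw$gene_symbol)] <- NA_character_
  if (nrow(raw) > 0) {
    for (i in seq_len(nrow(raw))) {
      row <- raw[i, ]
      if (!row$cycle %in% CYCLE_CODES)
        stopf("catalog row %d: unknown cycle code '%s'", i, row$cycle)
      if (!is_placeholder_id(row$marker_id) &&
          (is.na(row$db) || !accession_ok(row$marker_id, row$db)))
        stopf("catalog row %d: accession '%s' does not match db '%s'",
              i, row$marker_id, row$db)
    }
    dup <- duplicated(raw[, c("pathway", "marker_id")])
    if (any(dup))
      stopf("catalog row %d: duplicate (pathway, marker_id) pair", which(dup)[1])
  }
  if (is.null(base)) {
    out <- new_marker_catalog(raw)
  } else {
    entries <- base$entries
    keep <- !(normalize_pathway(entries$pathway) %in%
                normalize_pathway(raw$pathway))
    entries <- rbind(entries[keep, ], raw)
    # preserve built-in ordering for overridden pathways
    ord <- order(match(normalize_pathway(entries$pathway),
                       normalize_pathway(base$entries$pathway),
                       nomatch = nrow(base$entries) + 1L))
    out <- new_marker_catalog(entries[ord, ], base$replacements)
  }
  viol <- validate_catalog(out)
  if (length(viol) > 0)
    stopf("catalog %s is invalid:\n  %s", path, paste(viol, collapse = "\n  "))
  out
}

#' Write a catalog to TSV
#'
#' @param cat A `marker_catalog`.
#' @param path Output path.
#' @export
write_catalog <- function(cat, path) {
  utils::write.table(cat$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a marker catalog
#'
#' Checks the catalog invariants: accessions match their database pattern,
#' cycle codes are among C/N/P/S/Fe, (pathway, marker_id) pairs are unique,
#' each accession maps to exactly one pathway, and every KO-to-Pfam
#' replacement target is present as a Pfam entry. Violations are returned
#' as data, not raised.
#'
#' @param cat A `marker_catalog`.
#' @return Character vector of violation descriptions; empty if the catalog
#'   is valid.
#' @export
validate_catalog <- function(cat) {
  stopifnot(inherits(cat, "marker_catalog"))
  ent <- cat$entries
  out <- character()
  real <- !is_placeholder_id(ent$marker_id)
  bad_acc <- real & !accession_ok(ent$marker_id, ent$db)
  if (any(bad_acc))
    out <- c(out, sprintf("entry '%s': accession '%s' invalid for db '%s'",
                          ent$pathway[bad_acc], ent$marker_id[bad_acc],
                          ent$db[bad_acc]))
  bad_cycle <- !ent$cycle %in% CYCLE_CODES
  if (any(bad_cycle))
    out <- c(out, sprintf("entry '%s': unknown cycle code '%s'",
                          ent$pathway[bad_cycle], ent$cycle[bad_cycle]))
  dup_pair <- duplicated(ent[, c("pathway", "marker_id")])
  if (any(dup_pair))
    out <- c(out, sprintf("duplicate entry (pathway '%s', marker '%s')",
                          ent$pathway[dup_pair], ent$marker_id[dup_pair]))
  # a real accession must not map to two different pathways
  by_id <- split(normalize_pathway(ent$pathway[real]), ent$marker_id[real])
  multi <- names(by_id)[vapply(by_id, function(p) length(unique(p)) > 1, logical(1))]
  if (length(multi) > 0)
    out <- c(out, sprintf("marker '%s' maps to multiple pathways", multi))
  if (length(cat$replacements) > 0) {
    pfam_ids <- ent$marker_id[real & ent$db == "Pfam"]
    orphan <- !cat$replacements %in% pfam_ids
    if (any(orphan))
      out <- c(out, sprintf("replacement %s -> %s has no Pfam entry",
                            names(cat$replacements)[orphan],
                            cat$replacements[orphan]))
  }
  out
}

# marker accession -> pathway lookup, placeholders excluded, KO replacements
# folded onto their Pfam substitute's pathway
marker_to_pathway_map <- function(cat) {
  ent <- cat$entries
  real <- !is_placeholder_id(ent$marker_id)
  map <- stats::setNames(ent$pathway[real], ent$marker_id[real])
  if (length(cat$replacements) > 0) {
    tgt <- map[cat$replacements]
    ok <- !is.na(tgt)
    map <- c(map, stats::setNames(tgt[ok], names(cat$replacements)[ok]))
  }
  map
}

# pathway (normalised) -> cycle lookup
pathway_cycle_map <- function(cat) {
  stats::setNames(cat$entries$cycle, normalize_pathway(cat$entries$pathway))
}
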