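# shared internal helpers

TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")
CYCLE_CODES <- c("C", "N", "P", "S", "Fe")
UNASSIGNED <- "UNASSIGNED"

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical pathway key: case-insensitive, whitespace-normalised
normalize_pathway <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

is_placeholder_id <- function(marker_id) {
  startsWith(marker_id, "UNSET:")
}

# accession pattern per database
accession_ok <- function(marker_id, db) {
  pat <- c(KEGG = "^K[0-9]{5}$", Pfam = "^PF[0-9]{5}$", SYN = "^SYN[0-9]{5}$")
  ok <- rep(FALSE, length(marker_id))
  known <- db %in% names(pat)
  ok[known] <- mapply(function(id, d) grepl(pat[[d]], id), marker_id[known], db[known])
  ok
}

# upper-triangle unfold with a fixed (column-major) pair order
upper_vec <- function(m) m[upper.tri(m)]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_distance_matrix <- function(d, arg = deparse(substitute(d))) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stopf("%s must be a square matrix", arg)
  if (is.null(rownames(d)))
    stopf("%s must carry sample labels as dimnames", arg)
  if (max(abs(d - t(d))) > 1e-12)
    stopf("%s is not symmetric", arg)
  if (any(diag(d) != 0))
    stopf("%s has a nonzero diagonal", arg)
  invisible(d)
}

# seed-scoped evaluation; never touches the caller's RNG stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
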