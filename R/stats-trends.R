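#' Latitudinal trends of pathway abundance
#'
#' Fits, per pathway, a Gaussian generalized linear model (identity link,
#' equivalent to ordinary least squares) of the pathway's per-sample
#' proportion on latitude, and flags slopes significant at the two-sided
#' 0.05 level (t-test on the slope). Raw p-values are reported — the
#' significance flag uses no multiple-testing correction — with a
#' Benjamini-Hochberg adjusted column added for transparency.
#'
#' @param mat Proportion matrix, samples x pathways (rownames = sample
#'   IDs).
#' @param meta Metadata data frame with `sample_id` and `latitude`; must
#'   cover all samples in `mat`.
#' @return Data frame with one row per pathway: `pathway`, `slope`,
#'   `intercept`, `p_value`, `significant` (p < 0.05), `p_adjusted_bh`.
#'   Pathways with undefined fits (all-`NA` column) get `NA` rows.
#' @export
latitude_trends <- function(mat, meta) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stopf("latitude_trends: need >= 3 samples")
  lat <- meta$latitude[match(rownames(mat), meta$sample_id)]
  if (anyNA(lat))
    stopf("latitude_trends: metadata lacks sample(s): %s",
          paste(rownames(mat)[is.na(lat)], collapse = ", "))
  if (stats::var(lat) == 0) stopf("latitude_trends: latitude is constant")
  fit_one <- function(y) {
    if (all(is.na(y))) return(c(NA_real_, NA_real_, NA_real_))
    fit <- stats::glm(y ~ lat, family = stats::gaussian())
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2) return(c(NA_real_, sm[1, 1], NA_real_))
    c(sm[2, 1], sm[1, 1], sm[2, 4])
  }
  res <- t(apply(mat, 2, fit_one))
  out <- data.frame(pathway = colnames(mat),
                    slope = res[, 1], intercept = res[, 2],
                    p_value = res[, 3], stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out$p_adjusted_bh <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Spearman correlations between pathways and environmental variables
#'
#' Rank correlation (midranks for ties) between each pathway's per-sample
#' abundance and each numeric environmental variable, with two-sided
#' p-values from the t approximation. A constant variable yields `NA` with
#' a warning.
#'
#' @param mat Abundance matrix, samples x pathways.
#' @param meta Metadata data frame; all numeric columns other than
#'   latitude/longitude are used as environmental variables (latitude and
#'   longitude are included too, as the transect position is itself a
#'   gradient of interest).
#' @param env_vars Optional character vector restricting the variables.
#' @return List with matrices `rho` and `p_value` (pathways x variables).
#' @export
spearman_env <- function(mat, meta, env_vars = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 4) stopf("spearman_env: need >= 4 samples")
  idx <- match(rownames(mat), meta$sample_id)
  if (anyNA(idx))
    stopf("spearman_env: metadata lacks sample(s): %s",
          paste(rownames(mat)[is.na(idx)], collapse = ", "))
  meta <- meta[idx, , drop = FALSE]
  num <- names(meta)[vapply(meta, is.numeric, logical(1))]
  vars <- env_vars %||% num
  bad <- setdiff(vars, num)
  if (length(bad) > 0)
    stopf("spearman_env: non-numeric or missing variable(s): %s",
          paste(bad, collapse = ", "))
  rho <- p <- matrix(NA_real_, ncol(mat), length(vars),
                     dimnames = list(colnames(mat), vars))
  for (v in vars) {
    x <- meta[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warnf("spearman_env: variable '%s' is constant; correlations set to NA", v)
      next
    }
    for (j in seq_len(ncol(mat))) {
      y <- mat[, j]
      if (length(unique(y[!is.na(y)])) < 2) next
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
      rho[j, v] <- unname(ct$estimate)
      p[j, v] <- ct$p.value
    }
  }
  list(rho = rho, p_value = p)
}

#' Per-sample diversity table
#'
#' Shannon H' (nats) and richness of each sample's pathway counts, plus
#' their Pearson and Spearman correlations with latitude when metadata is
#' supplied.
#'
#' @param counts Count matrix, samples x pathways.
#' @param meta Optional metadata with `sample_id` and `latitude`.
#' @return List with `table` (sample_id, shannon, richness) and, if `meta`
#'   given, `latitude_correlation` (data frame: index, pearson_r,
#'   pearson_p, spearman_rho, spearman_p).
#' @export
diversity_table <- function(counts, meta = NULL) {
  counts <- as.matrix(counts)
  tab <- data.frame(
    sample_id = rownames(counts),
    shannon = apply(counts, 1, shannon),
    richness = apply(counts, 1, richness),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  out <- list(table = tab)
  if (!is.null(meta)) {
    lat <- meta$latitude[match(tab$sample_id, meta$sample_id)]
    corr <- function(y) {
      if (stats::var(y) == 0) # e.g. richness saturated at the pathway count
        return(c(pearson_r = NA_real_, pearson_p = NA_real_,
                 spearman_rho = NA_real_, spearman_p = NA_real_))
      pe <- stats::cor.test(lat, y)
      sp <- suppressWarnings(
        stats::cor.test(lat, y, method = "spearman", exact = FALSE))
      c(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
        spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
    }
    cc <- rbind(shannon = corr(tab$shannon), richness = corr(tab$richness))
    out$latitude_correlation <- data.frame(index = rownames(cc), cc,
                                           row.names = NULL)
  }
  out
}
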