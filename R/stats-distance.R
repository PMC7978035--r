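#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `latitude`, `longitude` and any number of
#' numeric environmental/soil columns (pH, MAT, MAP, humic/fulvic acid,
#' TOC, sesquioxides, ...).
#'
#' @param path TSV path.
#' @return A data frame with unique sample IDs; latitude/longitude validated.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  required <- c("sample_id", "latitude", "longitude")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0)
    stopf("metadata file %s lacks column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  validate_metadata(meta)
  meta
}

validate_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id))
    stopf("metadata: duplicated sample_id '%s'",
          meta$sample_id[duplicated(meta$sample_id)][1])
  if (any(meta$latitude < -90 | meta$latitude > 90))
    stopf("metadata: latitude outside [-90, 90]")
  if (any(meta$longitude < -180 | meta$longitude > 180))
    stopf("metadata: longitude outside [-180, 180]")
  invisible(meta)
}

#' Great-circle distance matrix between samples
#'
#' Haversine distance on a sphere of radius 6371 km, via
#' [geosphere::distHaversine()].
#'
#' @param meta Metadata data frame with `sample_id`, `latitude`,
#'   `longitude`.
#' @return Symmetric matrix of distances in km, labelled by sample ID.
#' @export
geographic_distance <- function(meta) {
  validate_metadata(meta)
  pts <- cbind(meta$longitude, meta$latitude)
  n <- nrow(pts)
  d <- matrix(0, n, n, dimnames = list(meta$sample_id, meta$sample_id))
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(pts[i, , drop = FALSE], pts,
                                       r = 6371) # km
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# Euclidean distance matrix from a single numeric variable (for MRM
# environmental predictors)
#' Pairwise absolute-difference distance matrix of one variable
#'
#' @param x Numeric vector.
#' @param labels Sample labels.
#' @return Symmetric labelled matrix of |x_i - x_j|.
#' @export
variable_distance <- function(x, labels) {
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(labels, labels)
  d
}

align_matrices <- function(ref, others) {
  labs <- rownames(ref)
  lapply(others, function(m) {
    check_distance_matrix(m, "predictor")
    if (!setequal(rownames(m), labs))
      stopf("distance matrices carry different sample labels")
    m[labs, labs]
  })
}

#' Distance-decay of community similarity
#'
#' Regresses community similarity (1 - dissimilarity) on geographic
#' distance over all sample pairs (upper triangle), and tests the slope by
#' a Mantel-style permutation: sample labels of the community matrix are
#' permuted jointly over rows and columns, the regression refitted, and the
#' permutation p-value computed with the add-one rule on |slope|, so p is
#' never exactly zero.
#'
#' @param d_comm Community dissimilarity matrix (e.g. [bray_curtis()]).
#' @param d_geo Geographic distance matrix on the same samples (km).
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed RNG seed for the permutations.
#' @return List with `slope` (similarity per km), `intercept`, `p_value`,
#'   `r_squared`, `n_pairs`, `n_perm`, `seed`.
#' @export
distance_decay <- function(d_comm, d_geo, n_perm = 999, seed = 0) {
  check_distance_matrix(d_comm)
  d_geo <- align_matrices(d_comm, list(d_geo))[[1]]
  if (n_perm < 99) stopf("distance_decay: n_perm must be >= 99")
  ut <- upper.tri(d_comm)
  x <- d_geo[ut]
  y <- 1 - d_comm[ut]
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_
  n <- nrow(d_comm)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      yb <- 1 - d_comm[p, p][ut]
      sb <- stats::lm.fit(cbind(1, x), yb)$coefficients[2]
      if (abs(sb) >= abs(slope) - 1e-15) cnt <- cnt + 1L
    }
    cnt
  })
  list(slope = unname(slope), intercept = unname(intercept),
       p_value = (1 + exceed) / (1 + n_perm),
       r_squared = r2, n_pairs = sum(ut), n_perm = n_perm, seed = seed)
}

#' Multiple regression on distance matrices (MRM)
#'
#' OLS of the unfolded upper triangle of a response distance matrix on the
#' unfolded triangles of one or more predictor distance matrices.
#' Inference is by Mantel permutation of the response: its rows and columns
#' are permuted jointly, the model refitted, and each |coefficient| (and
#' R^2) compared to the observed value; p-values use the add-one rule
#' p = (1 + #exceedances) / (1 + n_perm), so they lie in (0, 1\].
#'
#' @param d_resp Response distance matrix.
#' @param d_preds Named list of predictor distance matrices on the same
#'   samples.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed RNG seed.
#' @return An `mrm_result`: list with `coefficients` (named, incl.
#'   intercept), `r_squared`, `p_coefficients`, `p_r_squared`, `n_perm`,
#'   `seed`, `n_pairs`.
#' @export
mrm <- function(d_resp, d_preds, n_perm = 999, seed = 0) {
  check_distance_matrix(d_resp)
  if (length(d_preds) < 1) stopf("mrm: need at least one predictor")
  if (is.null(names(d_preds)) || any(!nzchar(names(d_preds))))
    names(d_preds) <- paste0("X", seq_along(d_preds))
  d_preds <- align_matrices(d_resp, d_preds)
  if (n_perm < 99) stopf("mrm: n_perm must be >= 99")
  ut <- upper.tri(d_resp)
  X <- cbind(`(Intercept)` = 1,
             vapply(d_preds, function(m) m[ut], numeric(sum(ut))))
  y <- d_resp[ut]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # name the most collinear predictor pair
    pv <- X[, -1, drop = FALSE]
    cm <- suppressWarnings(stats::cor(pv))
    cm[!upper.tri(cm)] <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    stopf("mrm: collinear predictors ('%s' and '%s'): design matrix is rank-deficient",
          colnames(pv)[worst[1]], colnames(pv)[worst[2]])
  }
  coefs <- qr.coef(qrX, y)
  fitted <- X %*% coefs
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum((y - fitted)^2) / tss else NA_real_
  n <- nrow(d_resp)
  # hat for fast refits: coef = H %*% y_perm
  H <- solve(crossprod(X), t(X))
  res <- with_seed(seed, {
    exceed_c <- numeric(length(coefs))
    exceed_r2 <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      yb <- d_resp[p, p][ut]
      cb <- H %*% yb
      exceed_c <- exceed_c + (abs(cb) >= abs(coefs) - 1e-15)
      rb <- 1 - sum((yb - X %*% cb)^2) / tss # tss invariant to permutation
      if (rb >= r2 - 1e-15) exceed_r2 <- exceed_r2 + 1L
    }
    list(c = exceed_c, r2 = exceed_r2)
  })
  structure(list(
    coefficients = coefs,
    r_squared = r2,
    p_coefficients = stats::setNames((1 + res$c) / (1 + n_perm), names(coefs)),
    p_r_squared = (1 + res$r2) / (1 + n_perm),
    n_perm = n_perm, seed = seed, n_pairs = sum(ut)
  ), class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("MRM over %d sample pairs, %d permutations (seed %d)\n",
              x$n_pairs, x$n_perm, x$seed))
  tab <- data.frame(coefficient = x$coefficients, p = x$p_coefficients)
  print(tab)
  cat(sprintf("R-squared: %.4f (p = %.4g)\n", x$r_squared, x$p_r_squared))
  invisible(x)
}
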