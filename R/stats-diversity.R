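#' Shannon diversity (natural log)
#'
#' H' = -sum p_i ln p_i over the positive entries of a count vector, with
#' p_i the relative abundances. Natural log, so the uniform k-vector scores
#' ln k.
#'
#' @param counts Nonnegative numeric vector with at least one positive
#'   entry.
#' @return H' in nats.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stopf("shannon: negative counts")
  tot <- sum(counts)
  if (tot <= 0) stopf("shannon: all counts are zero")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Richness
#'
#' Number of strictly positive entries of a count vector (number of
#' pathways/genes observed in a sample).
#'
#' @param counts Nonnegative numeric vector.
#' @return Integer count.
#' @export
richness <- function(counts) {
  sum(counts > 0)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(a, b) = sum |a_i - b_i| / sum (a_i + b_i) between sample rows of an
#' abundance matrix (counts or proportions). Computed with
#' [vegan::vegdist()]; returned as a full labelled symmetric matrix.
#'
#' @param mat Numeric matrix, samples as rows (rownames = sample IDs).
#' @return Symmetric matrix with zero diagonal, values in \[0, 1\].
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stopf("bray_curtis: need at least two samples")
  zero <- rowSums(mat) == 0
  if (any(zero))
    stopf("bray_curtis: sample(s) with all-zero abundances: %s",
          paste(rownames(mat)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(mat, method = "bray"))
  diag(d) <- 0
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres -D^2/2, eigendecomposes, and returns coordinates scaled
#' by the square root of the positive eigenvalues. Negative eigenvalues
#' (a non-Euclidean distance) are reported but excluded from the axes and
#' from the relative-eigenvalue denominator; no Cailliet/Lingoes correction
#' is applied. For a stable orientation, each axis is flipped so its first
#' nonzero loading is positive.
#'
#' @param d Distance matrix (square, symmetric, labelled).
#' @param k Number of axes requested; if fewer positive eigenvalues exist,
#'   fewer axes are returned with a warning.
#' @return List with `coordinates` (samples x k'), `eigenvalues` (all n,
#'   descending), `relative_eigenvalues` (positive eigenvalues / their sum).
#' @export
pcoa <- function(d, k = 2) {
  check_distance_matrix(d)
  if (k < 1) stopf("pcoa: k must be >= 1")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals), 1) * 1e-10
  pos <- which(vals > tol)
  k_eff <- min(k, length(pos))
  if (k_eff < k)
    warnf("pcoa: only %d positive eigenvalue(s); returning %d axis/axes",
          length(pos), k_eff)
  if (k_eff == 0) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(d), NULL))
  } else {
    idx <- pos[seq_len(k_eff)]
    coords <- eig$vectors[, idx, drop = FALSE] %*%
      diag(sqrt(vals[idx]), k_eff, k_eff)
    # sign convention: first nonzero loading of each axis positive
    for (j in seq_len(ncol(coords))) {
      nz <- which(abs(coords[, j]) > tol)
      if (length(nz) > 0 && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
    }
    dimnames(coords) <- list(rownames(d), paste0("PCo", seq_len(k_eff)))
  }
  rel <- if (length(pos) > 0) vals[pos] / sum(vals[pos]) else numeric()
  list(coordinates = coords, eigenvalues = vals, relative_eigenvalues = rel)
}
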