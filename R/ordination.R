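#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and scales eigenvectors by
#' the square root of their (positive) eigenvalues. Negative eigenvalues —
#' which arise when the dissimilarity is not Euclidean-embeddable, as Jaccard
#' generally is not — are reported but contribute zero coordinates; no
#' Lingoes/Cailliez correction is applied. When the input distances are
#' Euclidean, pairwise distances among the full-rank coordinates reproduce
#' them.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes number of coordinate axes to return (default
#'   `ncol(d) - 1`, the maximum).
#' @param tol eigenvalues with absolute value below `tol * max(abs(eig))` are
#'   treated as zero.
#' @return An object of class `viromark_pcoa`: list with `sample_ids`,
#'   `coordinates` (samples x axes), `eigenvalues` (all n, non-increasing)
#'   and `proportion_explained` (over positive eigenvalues; zero for
#'   non-positive axes).
#' @export
pcoa <- function(d, n_axes = ncol(d) - 1L, tol = 1e-10) {
  validate_dissimilarity(d, tol = 1e-8)
  n <- ncol(d)
  if (!is.numeric(n_axes) || length(n_axes) != 1L || n_axes < 1 || n_axes > n - 1L) {
    vm_validation_stop("`n_axes` must be between 1 and n_samples - 1")
  }
  n_axes <- as.integer(n_axes)
  a <- -0.5 * d^2
  centering <- diag(n) - matrix(1 / n, n, n)
  b <- centering %*% a %*% centering
  b <- (b + t(b)) / 2                      # symmetrize against rounding
  eig <- eigen(b, symmetric = TRUE)
  values <- eig$values
  cut <- tol * max(abs(values), 1e-300)
  pos <- values > cut
  coords <- matrix(0, n, n_axes)
  use <- which(pos)[seq_len(min(sum(pos), n_axes))]
  if (length(use)) {
    coords[, seq_along(use)] <- eig$vectors[, use, drop = FALSE] %*%
      diag(sqrt(values[use]), nrow = length(use))
  }
  pos_total <- sum(values[pos])
  prop <- rep(0, n_axes)
  if (pos_total > 0 && length(use)) prop[seq_along(use)] <- values[use] / pos_total
  ids <- if (!is.null(rownames(d))) rownames(d) else paste0("sample_", seq_len(n))
  rownames(coords) <- ids
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  structure(
    list(sample_ids = ids, coordinates = coords, eigenvalues = values,
         proportion_explained = prop),
    class = "viromark_pcoa"
  )
}

#' @export
print.viromark_pcoa <- function(x, ...) {
  cat("Principal coordinates analysis:", length(x$sample_ids), "samples,",
      ncol(x$coordinates), "axes\n")
  k <- min(3L, ncol(x$coordinates))
  cat("Proportion explained (first axes):",
      paste(sprintf("%.3f", x$proportion_explained[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}
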