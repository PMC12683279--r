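#' Shannon diversity index
#'
#' H = -sum(p_i * log(p_i)) over taxa with positive counts, with p_i the
#' within-sample proportion. Natural log by default (so H is in nats);
#' base-2 available for bits.
#'
#' @param counts non-negative numeric vector with at least one positive entry.
#' @param base log base, `"ln"` (default) or `"log2"`.
#' @return Shannon index, a single non-negative real.
#' @export
shannon_index <- function(counts, base = c("ln", "log2")) {
  base <- match.arg(base)
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    vm_validation_stop("`counts` must be a finite non-negative numeric vector")
  }
  pos <- counts[counts > 0]
  if (!length(pos)) vm_validation_stop("all-zero count vector has no defined diversity")
  p <- pos / sum(pos)
  h <- -sum(p * log(p))
  if (base == "log2") h <- h / log(2)
  h
}

#' Shannon index for every sample of a table
#'
#' @param table abundance matrix (taxa x samples).
#' @inheritParams shannon_index
#' @return Named numeric vector, one value per sample column.
#' @export
shannon_per_sample <- function(table, base = c("ln", "log2")) {
  validate_abundance_table(table)
  base <- match.arg(base)
  vapply(seq_len(ncol(table)),
         function(j) shannon_index(table[, j], base = base),
         numeric(1)) |> stats::setNames(colnames(table))
}

#' Jaccard dissimilarity between two presence/absence profiles
#'
#' `1 - |A intersect B| / |A union B|` over the sets of detected taxa, so 0
#' means the samples detect exactly the same taxa and 1 means they are
#' disjoint. Two empty profiles are defined as distance 0 (identical in
#' content) with a warning.
#'
#' @param a,b binary vectors of equal length (values 0/1 or logical).
#' @return Jaccard distance in \[0, 1\].
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b)) {
    vm_validation_stop("profiles differ in length: ", length(a), " vs ", length(b))
  }
  a <- as.logical(a)
  b <- as.logical(b)
  if (anyNA(a) || anyNA(b)) vm_validation_stop("profiles must not contain NA")
  union_n <- sum(a | b)
  if (union_n == 0) {
    vm_warn("both profiles are empty; Jaccard distance defined as 0")
    return(0)
  }
  1 - sum(a & b) / union_n
}

#' Pairwise Jaccard dissimilarity matrix over samples
#'
#' Computes [jaccard_distance()] between every pair of sample columns of a
#' presence matrix.
#'
#' @param presence binary matrix (taxa x samples), >= 2 samples.
#' @return Square symmetric matrix with zero diagonal and the sample ids as
#'   dimnames.
#' @export
jaccard_matrix <- function(presence) {
  validate_abundance_table(presence)
  if (any(presence != 0 & presence != 1)) {
    vm_validation_stop("presence matrix entries must be 0/1; run binarize() first")
  }
  n <- ncol(presence)
  if (n < 2L) vm_validation_stop("need >= 2 samples for a dissimilarity matrix")
  x <- presence > 0
  inter <- crossprod(x)                    # |A & B| for all pairs
  sizes <- diag(inter)
  union <- outer(sizes, sizes, "+") - inter
  if (any(diag(union) == 0)) {
    vm_warn("empty sample profile(s); distances involving two empty samples are 0")
  }
  d <- ifelse(union > 0, 1 - inter / union, 0)
  diag(d) <- 0
  dimnames(d) <- list(colnames(presence), colnames(presence))
  d
}

#' Validate a dissimilarity matrix
#'
#' @param d square numeric matrix.
#' @param tol symmetry tolerance (default 1e-12 relative to entries of order 1).
#' @return The matrix, after checking symmetry, zero diagonal and
#'   non-negativity.
#' @export
validate_dissimilarity <- function(d, tol = 1e-12) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    vm_validation_stop("dissimilarity must be a square numeric matrix")
  }
  if (max(abs(d - t(d))) > tol) vm_validation_stop("dissimilarity matrix is not symmetric")
  if (max(abs(diag(d))) > tol) vm_validation_stop("dissimilarity matrix has nonzero diagonal")
  if (any(d < -tol)) vm_validation_stop("dissimilarity matrix has negative entries")
  d
}

#' Write a dissimilarity matrix as square TSV
#' @param d validated square dissimilarity matrix with sample-id dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(d, path) {
  validate_dissimilarity(d, tol = 1e-8)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square dissimilarity matrix from TSV
#' @param path path written by [write_dissimilarity()].
#' @return Square numeric matrix with sample ids as dimnames.
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_dissimilarity(m, tol = 1e-8)
}
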