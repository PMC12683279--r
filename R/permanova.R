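#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Distance-based multivariate analysis of variance with a permutation test.
#' Sums of squares are computed directly from squared dissimilarities:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` analogously over
#' within-group pairs with each group's own size, and
#' `SS_between = SS_total - SS_within`. The pseudo-F statistic is
#' `(SS_between / (a - 1)) / (SS_within / (n - a))` for `a` groups, and the
#' p-value is the permutation estimator `(1 + #{F_perm >= F_obs}) /
#' (1 + n_permutations)` under random relabeling of samples.
#'
#' Only a one-way design is supported (a single grouping factor, e.g.
#' subject). The permutation stream is fully determined by `seed`; p-values
#' depend only on the grouping partition, not on the group label strings.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @param grouping group label per sample: a vector along `colnames(d)`, or a
#'   named vector matched to the matrix dimnames.
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `viromark_permanova`: list with `pseudo_f`,
#'   `r_squared`, `p_value`, `df_between`, `df_within`, `n_permutations`,
#'   `seed`.
#' @export
permanova <- function(d, grouping, n_permutations = 999L, seed = 1L) {
  validate_dissimilarity(d, tol = 1e-8)
  n <- ncol(d)
  if (!is.null(names(grouping)) && !is.null(colnames(d))) {
    if (!all(colnames(d) %in% names(grouping))) {
      vm_validation_stop("grouping is missing labels for some samples")
    }
    grouping <- grouping[colnames(d)]
  }
  if (length(grouping) != n) {
    vm_validation_stop("grouping length ", length(grouping), " != n samples ", n)
  }
  g <- as.integer(factor(grouping))
  a <- length(unique(g))
  if (a < 2L) vm_validation_stop("PERMANOVA needs >= 2 groups")
  if (max(tabulate(g)) == n) vm_validation_stop("one group holds all samples")
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    vm_validation_stop("`n_permutations` must be >= 1")
  }
  n_permutations <- as.integer(n_permutations)

  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  # SS_within for an assignment g, via group indicator algebra:
  #   sum_g (1_g' D2 1_g) / (2 n_g)
  group_sizes <- tabulate(g, nbins = a)
  ind <- function(gv) {
    m <- matrix(0, n, a)
    m[cbind(seq_len(n), gv)] <- 1
    m
  }
  ss_within_of <- function(gv) {
    m <- ind(gv)
    sum(colSums(m * (d2 %*% m)) / (2 * group_sizes))
  }
  f_of <- function(ssw) {
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  ssw_obs <- ss_within_of(g)
  f_obs <- f_of(ssw_obs)
  r2 <- (ss_total - ssw_obs) / ss_total

  perms <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) sample.int(n), integer(n))
  })
  # one big matmul: indicator blocks for all permutations side by side
  big <- matrix(0, n, a * n_permutations)
  rows <- as.vector(apply(perms, 2, function(p) p))
  cols <- rep(seq_len(n_permutations) - 1L, each = n) * a + rep(g, n_permutations)
  big[cbind(rows, cols)] <- 1
  prod_ <- d2 %*% big
  contrib <- colSums(big * prod_) / (2 * rep(group_sizes, n_permutations))
  ssw_perm <- colSums(matrix(contrib, nrow = a))
  f_perm <- vapply(ssw_perm, f_of, numeric(1))

  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
  structure(
    list(pseudo_f = f_obs, r_squared = r2, p_value = p,
         df_between = a - 1L, df_within = n - a,
         n_permutations = n_permutations, seed = as.integer(seed)),
    class = "viromark_permanova"
  )
}

#' @export
print.viromark_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (one-way): pseudo-F = %.4f (df %d, %d), R^2 = %.4f, p = %.4g (%d permutations)\n",
    x$pseudo_f, x$df_between, x$df_within, x$r_squared, x$p_value,
    x$n_permutations
  ))
  invisible(x)
}
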