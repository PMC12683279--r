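new_test_result <- function(statistic, p_value, method, alternative,
                            estimate = NULL, df = NULL) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         alternative = alternative, estimate = estimate, df = df),
    class = "viromark_test"
  )
}

#' @export
print.viromark_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, p = %.4g (%s)\n",
              x$method, x$statistic, x$p_value, x$alternative))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F = MS_between / MS_within with the
#' p-value from the F distribution. Intended for comparing per-sample Shannon
#' diversity across body sites or object types; each sample contributes one
#' observation and no repeated-measures structure is modelled.
#'
#' @param values numeric response vector.
#' @param groups group label per value (>= 2 groups).
#' @return A `viromark_test` with the F statistic, p-value and degrees of
#'   freedom.
#' @export
one_way_anova <- function(values, groups) {
  if (length(values) != length(groups)) {
    vm_validation_stop("`values` and `groups` differ in length")
  }
  if (anyNA(values) || anyNA(groups)) vm_validation_stop("NA in values or groups")
  g <- factor(groups)
  a <- nlevels(g)
  n <- length(values)
  if (a < 2L) vm_validation_stop("ANOVA needs >= 2 groups")
  if (n - a < 1L) vm_validation_stop("no residual degrees of freedom")
  grand <- mean(values)
  means <- tapply(values, g, mean)
  sizes <- tabulate(g)
  ss_between <- sum(sizes * (means[levels(g)] - grand)^2)
  ss_within <- sum((values - means[g])^2)
  if (ss_within <= 0) {
    vm_validation_stop("zero within-group variance; F is undefined")
  }
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  p <- stats::pf(f, a - 1, n - a, lower.tail = FALSE)
  new_test_result(f, p, method = "one_way_anova", alternative = "greater",
                  df = c(between = a - 1L, within = n - a))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic is the rank sum of `x` in the pooled sample (midranks for
#' ties). The exact p-value enumerates all `choose(n_x + n_y, n_x)`
#' assignments of the pooled values to the two samples; it is used when
#' `mode = "exact"`, or under `mode = "auto"` when `min(n_x, n_y) <= 8`,
#' there are no ties, and the enumeration stays below `max_enumeration`
#' assignments. Otherwise the normal approximation with tie correction and a
#' continuity correction of 1/2 is used. If all pooled values are identical
#' the approximate two-sided p is 1.
#'
#' @param x,y non-empty numeric vectors.
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `x` relative to `y`.
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @param max_enumeration cap on `choose(n_x + n_y, n_x)` for the automatic
#'   exact path (default 1e6); a forced `mode = "exact"` beyond the cap is an
#'   error.
#' @return A `viromark_test` with the rank-sum statistic and p-value; the
#'   `method` field records whether the exact or approximate path ran.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "less", "greater"),
                              mode = c("auto", "exact", "normal_approx"),
                              max_enumeration = 1e6) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) vm_validation_stop("empty sample")
  if (anyNA(x) || anyNA(y)) vm_validation_stop("NA in samples")
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(pooled) > 0
  n_comb <- choose(n, nx)

  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = min(nx, ny) <= 8 && !ties && n_comb <= max_enumeration
  )
  if (use_exact && n_comb > max_enumeration) {
    vm_validation_stop("exact enumeration too large (", format(n_comb),
                       " assignments); use mode = \"normal_approx\"")
  }

  if (use_exact) {
    # Enumerate every assignment of nx of the pooled ranks to sample x.
    combos <- utils::combn(n, nx)
    w_all <- colSums(matrix(r[combos], nrow = nx))
    p_le <- mean(w_all <= w + 1e-9)
    p_ge <- mean(w_all >= w - 1e-9)
    p <- switch(alternative,
      less = p_le,
      greater = p_ge,
      two_sided = min(1, 2 * min(p_le, p_ge))
    )
    return(new_test_result(w, p, method = "exact", alternative = alternative))
  }

  mu <- nx * (n + 1) / 2
  tie_tab <- table(pooled)
  sigma2 <- nx * ny * (n + 1) / 12 -
    nx * ny * sum(tie_tab^3 - tie_tab) / (12 * n * (n - 1))
  if (sigma2 <= 0) {
    # every pooled value identical: no evidence either way
    return(new_test_result(w, 1, method = "normal_approx",
                           alternative = alternative))
  }
  sigma <- sqrt(sigma2)
  cc <- 0.5
  p <- switch(alternative,
    less = stats::pnorm((w - mu + cc) / sigma),
    greater = stats::pnorm((w - mu - cc) / sigma, lower.tail = FALSE),
    two_sided = {
      z <- (w - mu - sign(w - mu) * cc) / sigma
      min(1, 2 * stats::pnorm(-abs(z)))
    }
  )
  new_test_result(w, p, method = "normal_approx", alternative = alternative)
}
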