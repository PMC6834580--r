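# One-sided two-sample tests used by the matched-resampling procedure, plus
# Benjamini-Hochberg adjustment. The KS statistic follows the usual ECDF
# convention: alternative "greater" means the CDF of x lies above the CDF of
# y somewhere, i.e. x is stochastically smaller.

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' With `alternative = "greater"` the statistic is
#' `D+ = sup_t (F_x(t) - F_y(t))`; a small p-value indicates that `x` is
#' stochastically *smaller* than `y` (its CDF lies above), which is the
#' expected signature of repressed targets when `x` holds target fold
#' changes. `alternative = "less"` uses `D- = sup_t (F_y(t) - F_x(t))`.
#' The default p-value is the one-sided asymptotic bound
#' `exp(-2 D^2 nm / (n + m))`, capped at 1; `exact = TRUE` enumerates all
#' assignments of the pooled sample (feasible for `n + m <= 16`) and returns
#' the exact permutation p-value.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param alternative `"greater"` or `"less"`.
#' @param exact Use exhaustive permutation enumeration for the p-value.
#' @return A list with elements `statistic` (D), `p_value`, `alternative`.
#' @examples
#' ks_one_sided(c(1, 2, 3), c(4, 5, 6), "greater") # D = 1, p = exp(-3)
#' @export
ks_one_sided <- function(x, y, alternative = c("greater", "less"),
                         exact = FALSE) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be nonempty.")
  if (anyNA(x) || anyNA(y)) abort("Samples must not contain NA.")
  d <- ks_stat(x, y, alternative)
  n <- length(x); m <- length(y)
  if (exact) {
    if (n + m > 16) abort("Exact enumeration is limited to n + m <= 16.")
    p <- ks_exact_p(x, y, alternative, d)
  } else {
    p <- min(1, exp(-2 * d^2 * n * m / (n + m)))
  }
  list(statistic = d, p_value = p, alternative = alternative)
}

# One-sided sup difference of ECDFs over the pooled points (ties collapsed).
ks_stat <- function(x, y, alternative) {
  n <- length(x); m <- length(y)
  w <- c(x, y)
  z <- cumsum(ifelse(order(w) <= n, 1 / n, -1 / m))
  ws <- sort(w)
  if (anyDuplicated(ws)) z <- z[c(which(diff(ws) != 0), n + m)]
  if (alternative == "greater") max(c(z, 0)) else -min(c(z, 0))
}

# Exact permutation p: all choose(n+m, n) assignments of the pooled values.
ks_exact_p <- function(x, y, alternative, d_obs) {
  pooled <- c(x, y)
  n <- length(x)
  combos <- combn(length(pooled), n)
  ds <- apply(combos, 2, function(ix) {
    ks_stat(pooled[ix], pooled[-ix], alternative)
  })
  mean(ds >= d_obs - 1e-12)
}

#' One-sided Fisher exact test (enrichment)
#'
#' For a 2x2 table with rows (target, non-target) and columns
#' (opposite-direction DE, not), the upper-tail hypergeometric probability of
#' the observed or a more extreme top-left cell - the probability of at least
#' this much enrichment of opposite-direction DE genes among targets under
#' fixed margins.
#'
#' @param tab A 2x2 matrix of nonnegative counts, or a length-4 vector
#'   `c(a, b, c, d)` filled row-wise.
#' @return The one-sided (greater) p-value.
#' @examples
#' fisher_one_sided(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)) # 1/6
#' @export
fisher_one_sided <- function(tab) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == c(2L, 2L)))
    v <- c(t(tab))
  } else {
    stopifnot(length(tab) == 4L)
    v <- tab
  }
  if (any(v < 0) || any(v != trunc(v))) {
    abort("Counts must be nonnegative integers.")
  }
  a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]
  # P(X >= a), X ~ Hypergeometric(white = a+b, black = c+d, drawn = a+c)
  phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values; `NA` entries are excluded from the family (the
#' number of tests is the number of non-NA p-values) and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}
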