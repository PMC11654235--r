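#' Two-sided Welch (unequal-variance) t-test
#'
#' Compares two samples with the unequal-variance t statistic and the
#' Welch-Satterthwaite degrees of freedom. Degenerate inputs are resolved by
#' convention rather than returning `NaN`: if both samples have zero variance
#' the p-value is 1 when the means are equal and 0 (flagged `"degenerate"`)
#' when they differ.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A list with elements `statistic`, `p`, `df` and `flag`
#'   (`"ok"` or `"degenerate"`).
#' @examples
#' welch_t(c(1, 2, 3), c(1, 2, 3, 4, 5))
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t() needs at least 2 finite observations per sample")
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, p = 1, df = NA_real_, flag = "ok"))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p = 0,
                df = NA_real_, flag = "degenerate"))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), flag = "ok")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a vector of p-values. `NA` values are excluded
#' from the family size and propagated as `NA` in the output; order is
#' preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Fisher's exact test with sample odds ratio
#'
#' Two-sided Fisher's exact test on a 2x2 table using the minimum-likelihood
#' summation convention (all tables with hypergeometric probability at most
#' that of the observed table). The reported odds ratio is the sample odds
#' ratio `ad/bc`, not the conditional MLE; zero cells yield 0 or `Inf` with a
#' flag.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, 2, byrow = TRUE)`.
#' @return A list with `odds_ratio`, `p` and `flag` (`"ok"` or `"zero_cell"`).
#' @examples
#' fisher_or(8, 2, 3, 7)
#' @export
fisher_or <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("cell counts must be non-negative integers")
  tab <- matrix(cnt, 2L, 2L, byrow = TRUE)
  if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 ||
      sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0)
    stop("all margins must be positive for an odds ratio")
  p <- stats::fisher.test(tab)$p.value
  zero <- any(cnt == 0)
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p = p, flag = if (zero) "zero_cell" else "ok")
}
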