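# Exact-test kernels used by the editing caller and downstream comparisons.

check_2x2 <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
    format_error("2x2 table cells must be non-negative integers")
  }
  if (a + b <= 0 || c + d <= 0) format_error("both row margins must be positive")
  invisible(TRUE)
}

#' One-sided Boschloo unconditional exact test
#'
#' Tests whether the success proportion of group 1 exceeds that of group 2
#' in a 2x2 table laid out as rows (group1: `a` successes, `b` failures;
#' group2: `c`, `d`).  The ordering statistic is the one-sided Fisher
#' conditional p (Boschloo's defining choice); the p-value is the supremum
#' over the nuisance common success probability of the probability of all
#' tables at least as extreme, evaluated on a uniform grid of `grid_size`
#' points in (0,1) plus the observed pooled proportion.  Uniformly at least
#' as powerful as the one-sided Fisher test (p is never larger).
#'
#' @param a,b,c,d non-negative integer cells.
#' @param grid_size nuisance-grid resolution (default 999).
#' @return p-value in (0, 1], with attribute `grid_size`.
#' @export
boschloo_one_sided <- function(a, b, c, d, grid_size = 999L) {
  check_2x2(a, b, c, d)
  n1 <- a + b; n2 <- c + d
  grid <- seq_len(grid_size) / (grid_size + 1)
  pooled <- (a + c) / (n1 + n2)
  if (pooled > 0 && pooled < 1) grid <- c(grid, pooled)
  p <- .boschloo_p_cpp(as.integer(a), as.integer(n1),
                       as.integer(c), as.integer(n2), grid)
  structure(p, grid_size = grid_size)
}

#' Fisher exact test for a 2x2 table
#'
#' Conditional hypergeometric test.  One-sided (`"greater"`: group 1 success
#' proportion larger) p is the upper hypergeometric tail at `a`; two-sided p
#' sums the probabilities of all tables whose point probability does not
#' exceed the observed one (the conventional exact definition, as in
#' `stats::fisher.test`).
#'
#' @param a,b,c,d non-negative integer cells (rows are groups, columns
#'   success/failure).
#' @param alternative `"two.sided"` or `"greater"`.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(a, b, c, d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  check_2x2(a, b, c, d)
  k <- a + c; n1 <- a + b; n2 <- c + d
  if (alternative == "greater") {
    return(min(1, phyper(a - 1, k, n1 + n2 - k, n1, lower.tail = FALSE)))
  }
  lo <- max(0L, k - n2); hi <- min(n1, k)
  x <- lo:hi
  d0 <- dhyper(x, k, n1 + n2 - k, n1)
  obs <- dhyper(a, k, n1 + n2 - k, n1)
  min(1, sum(d0[d0 <= obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; output order matches
#' input order and values are capped at 1.  `NA` p-values stay `NA`.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) format_error("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `r` and `p`.  Zero variance in either vector is
#'   signalled as an error of class `apobec3edit_degenerate`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) format_error("x and y must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) format_error("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stop(errorCondition("correlation undefined: zero variance",
                        class = c("apobec3edit_degenerate", "error")))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
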