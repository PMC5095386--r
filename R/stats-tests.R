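#' Spearman rank correlation with exact small-sample p-values
#'
#' Average-rank Spearman correlation, two-sided. The p-value is exact
#' (full permutation distribution) for n <= 9 without ties, and uses the
#' t-approximation otherwise. A constant vector yields an undefined rho,
#' returned flagged rather than as an error.
#'
#' @param x,y numeric vectors of equal length >= 3; pairs with `NA` are
#'   dropped.
#' @return List `rho, p, n, exact, flagged` (`flagged` is TRUE with `rho =
#'   NA` when either vector is constant).
#' @export
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, exact = FALSE,
                flagged = TRUE))
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  use_exact <- n <= 9 && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = use_exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       exact = use_exact, flagged = FALSE)
}

#' Brunner-Munzel test of stochastic equality between two samples
#'
#' Nonparametric two-sample test of the relative effect
#' p = P(X < Y) + 0.5 P(X = Y), robust to unequal variances, with the
#' t-approximation of Brunner & Munzel (2000). Two-sided.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return List `statistic, df, p, estimate, flagged`; `flagged` is TRUE
#'   (with `p = NA`) when the rank variance is degenerate (e.g. the two
#'   samples do not overlap at all, or all values are tied).
#' @export
brunner_munzel_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  rx <- rank(x); ry <- rank(y)
  m1 <- mean(r1); m2 <- mean(r2)
  pst <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r1 - rx - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - ry - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  if (n1 * v1 + n2 * v2 == 0)
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                estimate = pst, flagged = TRUE))
  stat <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(n1 * v1 + n2 * v2)
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, estimate = pst, flagged = FALSE)
}

#' Compare per-sample CO rates between two cross groups
#'
#' Applies [brunner_munzel_test()] to the per-sample genome-wide rates of
#' two groups (e.g. intraspecific vs interspecific F2s).
#'
#' @param rates_a,rates_b per-sample rates (cM/Mbp), >= 2 samples each.
#' @return As [brunner_munzel_test()].
#' @export
compare_groups <- function(rates_a, rates_b) {
  brunner_munzel_test(rates_a, rates_b)
}
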