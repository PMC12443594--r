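# log binomial coefficient
lchoose_ <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact conditional test: with margins fixed, the two-tailed p value sums
#' the hypergeometric probabilities of every table at least as extreme
#' (probability no larger than the observed one, up to a small numerical
#' tolerance).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list `p` (two-tailed), `odds_ratio` (sample).
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stopf("table must hold non-negative integers")
  a <- table[1, 1]
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); n <- r1 + r2
  if (n == 0) return(list(p = 1, odds_ratio = NaN))
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  x <- lo:hi
  logp <- lchoose_(r1, x) + lchoose_(r2, c1 - x) - lchoose_(n, c1)
  p_obs <- logp[x == a]
  p <- sum(exp(logp[logp <= p_obs + 1e-7]))
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(p = min(1, p), odds_ratio = or)
}

#' Mann-Whitney U test (two-tailed)
#'
#' Exact null distribution when both groups have at most `exact_limit`
#' observations: via the Wilcoxon rank-sum distribution without ties, or
#' by full enumeration of group assignments when ties are present (up to
#' 20000 assignments). Larger samples use the normal approximation with
#' tie and continuity corrections.
#'
#' @param groupA,groupB numeric vectors.
#' @param exact_limit switchover group size (default 12).
#' @return list `U` (for group A), `p` (two-tailed), `method`.
#' @export
mann_whitney_u <- function(groupA, groupB, exact_limit = 12) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 1 || nB < 1) stopf("both groups must be non-empty")
  r <- rank(c(groupA, groupB))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- anyDuplicated(c(groupA, groupB)) > 0
  if (!ties && max(nA, nB) <= exact_limit) {
    p <- 2 * min(stats::pwilcox(U, nA, nB),
                 1 - stats::pwilcox(U - 1, nA, nB))
    return(list(U = U, p = min(1, p), method = "exact"))
  }
  if (ties && choose(nA + nB, nA) <= 20000) {
    # exact permutation distribution under ties, by full enumeration
    mu <- nA * nB / 2
    combos <- utils::combn(nA + nB, nA)
    us <- colSums(matrix(r[combos], nrow = nA)) - nA * (nA + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = p, method = "exact_ties"))
  }
  mu <- nA * nB / 2
  tie_tab <- table(c(groupA, groupB))
  n <- nA + nB
  sigma2 <- nA * nB / 12 *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Wilcoxon signed-rank test (two-tailed)
#'
#' Zero differences are dropped (all zero: p = 1 with a warning). Exact
#' null distribution when at most `exact_limit` non-zero pairs: via the
#' signed-rank distribution without ties, or by enumeration of all sign
#' vectors under tied absolute differences. Larger samples use the normal
#' approximation with tie correction.
#'
#' @param x,y paired numeric vectors, or differences in `x` when `y` is
#'   NULL.
#' @param exact_limit switchover size (default 12).
#' @return list `W` (positive-rank sum), `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 12) {
  d <- if (is.null(y)) x else x - y
  if (length(d) == 0) stopf("no pairs")
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(W = 0, p = 1, method = "degenerate"))
  }
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= exact_limit) {
    p <- 2 * min(stats::psignrank(W, n), 1 - stats::psignrank(W - 1, n))
    return(list(W = W, p = min(1, p), method = "exact"))
  }
  if (ties && n <= exact_limit) {
    # exact distribution under tied ranks: enumerate all sign vectors
    mu <- n * (n + 1) / 4
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- signs %*% r
    p <- mean(abs(ws - mu) >= abs(W - mu) - 1e-9)
    return(list(W = W, p = p, method = "exact_ties"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(list(W = W, p = 1, method = "normal"))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  list(W = W, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n), by direct summation of the
#' probability mass.
#'
#' @param k observed successes in the draw.
#' @param K successes in the population.
#' @param n draws.
#' @param N population size.
#' @return the upper-tail probability.
#' @export
hypergeometric_upper <- function(k, K, n, N) {
  stopifnot(K <= N, n <= N, k >= 0)
  hi <- min(K, n)
  if (k > hi) return(0)
  x <- k:hi
  sum(exp(lchoose_(K, x) + lchoose_(N - K, n - x) - lchoose_(N, n)))
}

#' Build the above/below-threshold x group contingency table
#'
#' Counts distinct junctions above and below the control threshold per
#' group, the figure-level comparison behind "more distinct SJs above
#' threshold in patients who later relapse".
#'
#' @param quant_tables list of thresholded [quantify()] tables (one per
#'   sample; `above_threshold` must be set, see [apply_threshold()]).
#' @param design data.frame `sample_id`, `group` (two levels).
#' @param threshold_model optional [fit_threshold()] model applied to any
#'   table whose `above_threshold` is still NA.
#' @return 2x2 matrix, rows above/below, columns the group levels.
#' @export
build_threshold_contingency <- function(quant_tables, design,
                                        threshold_model = NULL) {
  groups <- unique(design$group)
  if (length(groups) != 2) stopf("design must have exactly two groups")
  counts <- matrix(0L, 2, 2,
                   dimnames = list(c("above", "below"), groups))
  for (tb in quant_tables) {
    sid <- unique(tb$experiment_id)
    g <- design$group[match(sid, design$sample_id)]
    if (any(is.na(g))) stopf("sample %s missing from design", sid)
    if (anyNA(tb$above_threshold)) {
      if (is.null(threshold_model))
        stopf("table not thresholded and no threshold model given")
      tb <- apply_threshold(tb, threshold_model)
    }
    counts["above", g] <- counts["above", g] + sum(tb$above_threshold)
    counts["below", g] <- counts["below", g] + sum(!tb$above_threshold)
  }
  counts
}
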