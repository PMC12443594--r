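test_that("fisher_2x2 matches reference and is symmetric", {
  expect_equal(fisher_2x2(matrix(c(1, 0, 0, 1), 2))$p, 1)
  tb <- matrix(c(8, 1, 2, 9), 2)
  expect_equal(fisher_2x2(tb)$p, stats::fisher.test(tb)$p.value,
               tolerance = 1e-10)
  expect_equal(fisher_2x2(tb)$p, fisher_2x2(t(tb))$p, tolerance = 1e-12)
  expect_error(fisher_2x2(matrix(c(-1, 0, 0, 1), 2)), "non-negative")
})

test_that("exact tests agree with stats oracles for all tables n <= 10", {
  # full sweep over small 2x2 tables
  for (a in 0:3) for (b in 0:3) for (cc in 0:2) for (d in 0:2) {
    if (a + b + cc + d == 0) next
    tb <- matrix(c(a, cc, b, d), 2)
    expect_equal(fisher_2x2(tb)$p, stats::fisher.test(tb)$p.value,
                 tolerance = 1e-9,
                 info = paste(a, b, cc, d))
  }
})

test_that("Mann-Whitney: exact small-sample p by enumeration", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  res <- mann_whitney_u(a, b)
  expect_equal(res$U, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p, oracle_mwu_p(a, b), tolerance = 1e-12)
  set.seed(61)
  for (i in 1:10) {
    a <- round(rnorm(sample(2:5, 1)), 3)
    b <- round(rnorm(sample(2:5, 1)), 3)
    res <- mann_whitney_u(a, b)
    expect_equal(res$p, oracle_mwu_p(a, b), tolerance = 1e-9)
  }
  # label swap invariance
  expect_equal(mann_whitney_u(a, b)$p, mann_whitney_u(b, a)$p)
  # small tied samples switch to exact enumeration
  res_t <- mann_whitney_u(c(1, 1, 2), c(1, 2, 2))
  expect_equal(res_t$method, "exact_ties")
  expect_equal(res_t$p, oracle_mwu_p(c(1, 1, 2), c(1, 2, 2)),
               tolerance = 1e-12)
  # large tied samples use the corrected normal approximation
  set.seed(64)
  big <- mann_whitney_u(sample(1:5, 20, TRUE), sample(1:5, 20, TRUE))
  expect_equal(big$method, "normal")
  expect_true(big$p >= 0 && big$p <= 1)
})

test_that("Wilcoxon signed-rank: exact and degenerate behaviour", {
  d <- c(1.2, -0.5, 2.1, 0.7, -0.1)
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$method, "exact")
  expect_equal(res$p, oracle_signrank_p(d), tolerance = 1e-9)
  expect_warning(res0 <- wilcoxon_signed_rank(rep(0, 5)), "zero")
  expect_equal(res0$p, 1)
  # paired interface
  x <- c(3, 5, 1); y <- c(1, 2, 0.5)
  expect_equal(wilcoxon_signed_rank(x, y)$p,
               wilcoxon_signed_rank(x - y)$p)
})

test_that("hypergeometric upper tail equals direct summation", {
  expect_equal(hypergeometric_upper(3, 10, 5, 50),
               1 - stats::phyper(2, 10, 40, 5), tolerance = 1e-12)
  expect_equal(hypergeometric_upper(0, 5, 3, 20), 1)
  expect_equal(hypergeometric_upper(6, 5, 6, 20), 0)  # impossible k
  set.seed(62)
  for (i in 1:20) {
    N <- sample(5:40, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometric_upper(k, K, n, N),
                 1 - stats::phyper(k - 1, K, N - K, n),
                 tolerance = 1e-12)
  }
})

test_that("threshold contingency counts distinct junctions per group", {
  mk <- function(id, vals, above) {
    data.frame(junction_id = sprintf("%s_j%d", id, seq_along(vals)),
               raw_reads = 1, normalized_reads = vals,
               above_threshold = above, experiment_id = id,
               assay = "signal")
  }
  design <- data.frame(sample_id = c("s1", "s2"),
                       group = c("relapse", "non_relapse"))
  tabs <- list(mk("s1", c(0.5, 0.4, 0.001), c(TRUE, TRUE, FALSE)),
               mk("s2", c(0.002, 0.001), c(FALSE, FALSE)))
  ct <- build_threshold_contingency(tabs, design)
  expect_equal(ct["above", "relapse"], 2)
  expect_equal(ct["below", "non_relapse"], 2)
  expect_equal(sum(ct), 5)   # counts conserved
  # all junctions below threshold: zero column, Fisher p = 1
  tabs0 <- list(mk("s1", c(0.001, 0.002), c(FALSE, FALSE)),
                mk("s2", c(0.001, 0.002), c(FALSE, FALSE)))
  ct0 <- build_threshold_contingency(tabs0, design)
  expect_equal(sum(ct0["above", ]), 0)
  expect_equal(fisher_2x2(ct0)$p, 1)
  expect_error(build_threshold_contingency(
    tabs, data.frame(sample_id = "s1", group = "relapse")), "two groups")
})

test_that("replication contrast is detected by the threshold contingency", {
  # relapse-like junctions replicate (r = 1), non-relapse and healthy
  # controls dilute (r = 0); per-cell SJ levels carry lognormal
  # measurement noise. Fisher on the above/below-threshold table should
  # separate the groups in >= 80% of seeded runs at 30 + 30 junctions.
  level <- function(r, n, t = 6) {
    # per-junction per-cell SJ level after t divisions
    base <- if (r == 1) 1 else 1 / 2^t
    base * rlnorm(n, 0, 0.25)
  }
  mk_tab <- function(vals, id) {
    data.frame(junction_id = sprintf("%s_j%d", id, seq_along(vals)),
               raw_reads = 1, normalized_reads = vals,
               above_threshold = NA, experiment_id = id, assay = "signal")
  }
  hits <- 0
  for (seed in 1:100) {
    set.seed(700 + seed)
    ctrl <- mk_tab(level(0, 10), "HB")
    rel <- mk_tab(level(1, 30), "rel")
    non <- mk_tab(level(0, 30), "non")
    model <- fit_threshold(list(ctrl))
    design <- data.frame(sample_id = c("rel", "non"),
                         group = c("relapse", "non_relapse"))
    ct <- build_threshold_contingency(
      list(apply_threshold(rel, model), apply_threshold(non, model)),
      design)
    if (fisher_2x2(ct)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 80)
})

test_that("p values live in [0, 1] and survive group swaps", {
  set.seed(63)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(7)
    p1 <- mann_whitney_u(a, b)$p
    p2 <- mann_whitney_u(b, a)$p
    expect_gte(p1, 0); expect_lte(p1, 1)
    expect_equal(p1, p2)
    tb <- matrix(rpois(4, 4), 2)
    expect_equal(fisher_2x2(tb)$p, fisher_2x2(tb[2:1, 2:1])$p,
                 tolerance = 1e-12)
  }
})
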