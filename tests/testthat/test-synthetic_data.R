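test_that("pure dilution with even segregation follows 1/2^t exactly", {
  cfg <- sim_config(seed = 1, n_founders = 1, divisions = 6,
                    esc_replication_prob = 0, segregation = "even",
                    secondary_prob = 0)
  tr <- simulate_population(cfg, fix_locus, fix_db)
  expect_equal(nrow(tr$cells), 64)
  expect_equal(tr$totals$rec_copies, 64)
  # one surviving circle in 64 cells: mean per-cell copies = 1/64 (1.6%)
  expect_equal(tr$totals$sj_copies, 1)
  expect_equal(tr$totals$sj_copies / tr$totals$rec_copies, 1 / 64)
})

test_that("faithful replication (r = 1) keeps one copy per cell", {
  cfg <- sim_config(seed = 2, n_founders = 3, divisions = 5,
                    esc_replication_prob = 1, segregation = "even",
                    secondary_prob = 0)
  tr <- simulate_population(cfg, fix_locus, fix_db)
  expect_true(all(tr$copies$copies == 1))
  expect_equal(nrow(tr$copies), nrow(tr$cells))
  expect_equal(tr$totals$sj_copies, tr$totals$rec_copies)
})

test_that("copy number matches the branching-process expectation", {
  # E[total copies after t divisions] = (1+r)^t per initial circle
  cfg <- sim_config(seed = 3, n_founders = 400, divisions = 6,
                    esc_replication_prob = 0.5, secondary_prob = 0)
  tr <- simulate_population(cfg, fix_locus, fix_db)
  expected <- 1.5^6
  got <- mean(tr$totals$sj_copies)
  mc_sd <- stats::sd(tr$totals$sj_copies) / sqrt(nrow(tr$totals))
  expect_lt(abs(got - expected), 5 * mc_sd + 0.5)
})

test_that("segregation conserves copies for every r", {
  set.seed(42)
  for (r in c(0, 0.3, 1)) {
    for (rep in 1:20) {
      copies <- rpois(8, 3)
      out <- esctools:::segregate_once(copies, r, "binomial")
      d1 <- out[1:8]; d2 <- out[9:16]
      expect_true(all(d1 + d2 >= copies))       # duplication only adds
      expect_true(all(d1 + d2 <= 2 * copies))
      if (r == 0) expect_equal(d1 + d2, copies) # no creation or loss
      if (r == 1) expect_equal(d1 + d2, 2 * copies)
      ev <- esctools:::segregate_once(copies, 0, "even")
      expect_equal(ev[1:8] + ev[9:16], copies)
      expect_true(all(abs(ev[1:8] - ev[9:16]) <= 1))
    }
  }
})

test_that("SJ:Rec trajectory halves per division at r=0, flat at r=1", {
  ratio_at <- function(r, t) {
    cfg <- sim_config(seed = 5, n_founders = 300, divisions = t,
                      esc_replication_prob = r, secondary_prob = 0)
    tr <- simulate_population(cfg, fix_locus, fix_db)
    sum(tr$totals$sj_copies) / sum(tr$totals$rec_copies)
  }
  r0 <- vapply(1:4, function(t) ratio_at(0, t), numeric(1))
  # exactly halves: copies are conserved, cells double
  expect_equal(r0, 1 / 2^(1:4))
  r1 <- vapply(1:4, function(t) ratio_at(1, t), numeric(1))
  expect_equal(r1, rep(1, 4))
})

test_that("WGS reads: junction-spanning fraction matches f/L", {
  cfg <- sim_config(seed = 6, n_founders = 1, divisions = 0,
                    esc_replication_prob = 0, secondary_prob = 0)
  tr <- simulate_population(cfg, fix_wide_locus, fix_wide_db,
                            junction_ids = "SJ_J1_V1")
  ent <- fix_wide_db[fix_wide_db$junction_id == "SJ_J1_V1", ]
  L <- ent$circle_end - ent$circle_start
  wgs <- simulate_wgs_reads(tr, fix_wide_locus, cfg,
                            circle_coverage = 700, genome_coverage = 0)
  frag <- unique(wgs$reads[, c("qname", "frag_spans_sj")])
  n <- nrow(frag)
  phat <- mean(frag$frag_spans_sj)
  p <- cfg$wgs_fragment_mean / L
  expect_gt(n, 2000)
  expect_lt(abs(phat - p), 4 * sqrt(p * (1 - p) / n) + 0.005)
})

test_that("WGS reads: no circles means no junction-spanning reads", {
  cfg <- sim_config(seed = 7, n_founders = 1, divisions = 3,
                    esc_replication_prob = 0, secondary_prob = 0)
  tr <- simulate_population(cfg, fix_wide_locus, fix_wide_db)
  tr$totals$sj_copies <- 0L
  tr$copies <- tr$copies[0, ]
  wgs <- simulate_wgs_reads(tr, fix_wide_locus, cfg)
  expect_equal(sum(wgs$reads$spans_sj), 0)
  expect_true(all(wgs$reads$origin == "genome"))
})

test_that("simulators are bit-reproducible from (config, seed)", {
  cfg <- sim_config(seed = 8, n_founders = 2, divisions = 3)
  t1 <- simulate_population(cfg, fix_locus, fix_db)
  t2 <- simulate_population(cfg, fix_locus, fix_db)
  expect_identical(t1, t2)
  w1 <- simulate_wgs_reads(t1, fix_locus, cfg, circle_coverage = 3,
                           genome_coverage = 0.5)
  w2 <- simulate_wgs_reads(t2, fix_locus, cfg, circle_coverage = 3,
                           genome_coverage = 0.5)
  expect_identical(w1, w2)
  l1 <- simulate_lam_reads(t1, fix_locus, cfg, "signal", total_reads = 100)
  l2 <- simulate_lam_reads(t2, fix_locus, cfg, "signal", total_reads = 100)
  expect_identical(l1, l2)
})

test_that("LAM reads start with the nested primer and overlap correctly", {
  cfg <- sim_config(seed = 9, n_founders = 3, divisions = 2,
                    seq_error_rate = 0)
  tr <- simulate_population(cfg, fix_locus, fix_db)
  primers <- design_primers(fix_locus,
                            amplicon_len = cfg$lam_amplicon_len)
  rd <- simulate_lam_reads(tr, fix_locus, cfg, "signal",
                           total_reads = 150)
  sig_primers <- primers$seq[primers$assay == "signal"]
  starts <- substr(rd$r1, 1, 20)
  expect_true(all(starts %in% sig_primers))
  # amplicon 320, reads 2 x 250: mates overlap by 2*250 - 320 = 180
  mg <- merge_pairs(rd$r1, rd$r2)
  expect_true(all(mg$merged))
  expect_true(all(nchar(mg$seq) == cfg$lam_amplicon_len))
})

test_that("LAM read counts are proportional to copy numbers", {
  cfg <- sim_config(seed = 10, lam_noise_sd = 0)
  counts <- data.frame(junction_id = c("SJ_J1_V1", "SJ_J2_V2"),
                       copies = c(100, 50))
  rd <- simulate_lam_reads_from_counts(fix_locus, fix_db, counts, cfg,
                                       "signal", total_reads = 3000)
  tab <- table(rd$reads$junction_id)
  frac <- tab[["SJ_J1_V1"]] / sum(tab)
  # binomial sampling around 2/3
  expect_lt(abs(frac - 2 / 3), 4 * sqrt(2 / 9 / 3000))
})

test_that("SV planting is deterministic and exactly proportioned", {
  svset <- simulate_sv_set(n_sv = 40,
                           proportions = c(none = 0.5, single = 0.35,
                                           double = 0.15),
                           locus = fix_locus, seed = 5)
  tab <- table(svset$svs$category_truth)
  expect_equal(as.integer(tab[c("none", "single", "double")]),
               c(20, 14, 6))
  # reintegration inserts align inside the antigen receptor locus
  re <- svset$svs[svset$svs$mechanism_truth == "reintegration", ]
  for (ins in re$insert_seq) {
    expect_true(grepl(ins, fix_locus$sequence, fixed = TRUE))
  }
  # none-class windows are free of hits at the scanner threshold
  noneb <- svset$svs[svset$svs$category_truth == "none", ][1:5, ]
  for (i in seq_len(nrow(noneb))) {
    ann <- annotate_breakpoint(noneb[i, ], svset$genome)
    expect_equal(ann$category, "none")
  }
  expect_error(simulate_sv_set(n_sv = 10,
                               proportions = c(none = 0.5, single = 0.4,
                                               double = 0.3),
                               locus = fix_locus, seed = 1), "sum to 1")
})
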