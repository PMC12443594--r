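test_that("demultiplex assigns uniquely, ties go unassigned, reads conserve", {
  primers <- data.frame(primer_id = c("P1", "P2"),
                        seq = c("ACGTACGTACGTACGTACGT",
                                "ACGTACGTACGTACGTACGA"))
  r <- c(a = paste0("ACGTACGTACGTACGTACGT", strrep("G", 50)),  # exact P1
         b = paste0("ACGTACGTACGTACGTACGC", strrep("G", 50)),  # 1 mm both
         c = paste0("TTTTTTTTTTTTTTTTTTTT", strrep("G", 50)))  # none
  d <- demultiplex(r, primers, max_mismatch = 1)
  expect_equal(d$bins$P1, "a")
  expect_equal(d$bins$P2, character(0))
  expect_setequal(d$unassigned, c("b", "c"))
  expect_equal(sum(lengths(d$bins)) + length(d$unassigned), length(r))
  expect_error(demultiplex(r, rbind(primers, primers)), "duplicate")
})

test_that("merge_pair merges by best overlap, falls back to read 1", {
  set.seed(31)
  amp <- random_dna(470)
  r1 <- substr(amp, 1, 250)
  r2 <- revcomp(substr(amp, 221, 470))
  m <- merge_pair(r1, r2)   # perfect 30 bp overlap
  expect_true(m$merged)
  expect_equal(m$overlap, 30)
  expect_equal(nchar(m$seq), 470)
  expect_identical(m$seq, amp)
  # unrelated reads: no admissible overlap, read 1 returned with flag
  m2 <- merge_pair(random_dna(250), random_dna(250))
  expect_false(m2$merged)
  expect_equal(nchar(m2$seq), 250)
})

test_that("merge_pair equals exhaustive shift enumeration", {
  set.seed(32)
  brute <- function(r1, r2, min_overlap = 20, rate = 0.1) {
    a <- strsplit(r1, "")[[1]]
    b <- strsplit(revcomp(r2), "")[[1]]
    best <- c(o = 0, m = -1)
    for (o in min_overlap:min(length(a), length(b))) {
      mm <- sum(a[(length(a) - o + 1):length(a)] != b[1:o])
      if (mm / o <= rate && (o - mm) > best["m"]) best <- c(o = o, m = o - mm)
    }
    best[["o"]]
  }
  for (i in 1:20) {
    amp <- random_dna(sample(300:460, 1))
    r1 <- substr(amp, 1, 250)
    r2 <- revcomp(substr(amp, nchar(amp) - 249, nchar(amp)))
    expect_equal(merge_pair(r1, r2)$overlap, brute(r1, r2))
  }
})

test_that("assignment matches truth on clean reads, rejects noise", {
  sig <- fix_db[fix_db$kind == "signal", ]
  idx <- esctools:::build_seed_index(sig)
  cfg <- sim_config(seed = 33, seq_error_rate = 0)
  for (jid in sig$junction_id[c(1, 4, 7)]) {
    ent <- sig[sig$junction_id == jid, ]
    a <- assign_junction(ent$ref_seq, sig, idx)
    expect_equal(a$junction_id, jid)
    expect_equal(a$identity, 1.0)
  }
  set.seed(33)
  a <- assign_junction(random_dna(300), sig, idx)
  expect_equal(a$status, "unassigned")
})

test_that("seeded assignment agrees with exhaustive Smith-Waterman", {
  sig <- fix_db[fix_db$kind == "signal", ]
  set.seed(34)
  cfg <- sim_config(seed = 34, seq_error_rate = 0.02)
  counts <- data.frame(junction_id = sig$junction_id,
                       copies = rep(10, nrow(sig)))
  rd <- simulate_lam_reads_from_counts(fix_locus, fix_db, counts, cfg,
                                       "signal", total_reads = 40)
  mg <- merge_pairs(rd$r1, rd$r2)
  asn <- assign_junctions(mg, sig)
  for (i in seq_len(nrow(mg))) {
    if (asn$status[i] != "assigned") next
    want <- oracle_best_entry(mg$seq[i], sig)
    if (!want$tie) expect_equal(asn$junction_id[i], want$junction_id)
  }
})

test_that("quantify normalizes by total assay reads", {
  asn <- data.frame(read_id = sprintf("r%d", 1:100),
                    junction_id = rep(c("SJ_A", NA), c(50, 50)),
                    status = rep(c("assigned", "unassigned"), c(50, 50)))
  q <- quantify(asn, "e1", "signal", total_reads = 1000)
  expect_equal(q$raw_reads, 50)
  expect_equal(q$normalized_reads, 0.05)
  # doubling every raw count leaves normalized values unchanged
  asn2 <- rbind(asn, asn)
  q2 <- quantify(asn2, "e1", "signal", total_reads = 2000)
  expect_equal(q2$normalized_reads, q$normalized_reads)
  expect_error(quantify(asn, "e1", "signal", total_reads = 0), "zero")
  # assigned-only denominator mode
  qa <- quantify(asn, "e1", "signal", denominator = "assigned")
  expect_equal(qa$normalized_reads, 1)
})

test_that("threshold is the control maximum and strictly exceeded", {
  ctrl <- data.frame(junction_id = c("a", "b"), raw_reads = c(3, 1),
                     normalized_reads = c(0.003, 0.001),
                     above_threshold = NA, experiment_id = "HB1",
                     assay = "signal")
  model <- fit_threshold(list(ctrl))
  expect_equal(model$threshold, 0.003)
  smp <- ctrl
  smp$normalized_reads <- c(0.003, 0.03)
  smp <- apply_threshold(smp, model)
  expect_equal(smp$above_threshold, c(FALSE, TRUE))  # 0.003 is NOT above
  # controls threshold themselves to zero positives
  expect_equal(sum(apply_threshold(ctrl, model)$above_threshold), 0)
  # adding a control can only raise the threshold
  ctrl2 <- ctrl
  ctrl2$normalized_reads <- c(0.01, 0.002)
  expect_gte(fit_threshold(list(ctrl, ctrl2))$threshold, model$threshold)
  expect_error(fit_threshold(list()), "control")
})

test_that("the pipeline never invents reads and keeps ids unique", {
  cfg <- sim_config(seed = 35, n_founders = 3, divisions = 3)
  tr <- simulate_population(cfg, fix_locus, fix_db)
  rd <- simulate_lam_reads(tr, fix_locus, cfg, "signal",
                           total_reads = 200)
  primers <- design_primers(fix_locus)
  res <- lam_call(rd$r1, rd$r2, fix_db[fix_db$kind == "signal", ],
                  primers, "e1", "signal")
  expect_true(all(res$assignments$read_id %in% names(rd$r1)))
  expect_false(any(duplicated(res$assignments$read_id)))
  expect_equal(sum(res$demux$bin_sizes) + res$demux$unassigned,
               length(rd$r1))
})

test_that("reads from inversional events never hit signal entries", {
  inv <- build_locus(locus_config(
    v_orientation = c("inversional", "deletional", "deletional"),
    seed = 7))
  db <- enumerate_junctions(inv)
  cfg <- sim_config(seed = 36, seq_error_rate = 0)
  # coding reads from the inversional V1 junctions
  counts <- data.frame(
    junction_id = db$junction_id[db$kind == "coding" &
                                   db$partnerB == "V1"],
    copies = 20)
  rd <- simulate_lam_reads_from_counts(inv, db, counts, cfg, "coding",
                                       total_reads = 60)
  mg <- merge_pairs(rd$r1, rd$r2)
  asn <- assign_junctions(mg, db[db$kind == "signal", ])
  expect_true(all(asn$status != "assigned"))
})
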