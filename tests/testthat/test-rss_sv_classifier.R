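consensus_rss <- function(spacer_len = 12) {
  # random spacer: poly-base spacers would let the nonamer model score at
  # unintended offsets
  paste0("CACAGTG", random_dna(spacer_len), "ACAAAAACC")
}

test_that("consensus RSS scores maximally on both strands", {
  set.seed(51)
  pwm <- rss_pwm()
  s <- paste0(random_dna(200), consensus_rss(12), random_dna(200))
  hits <- scan_rss(s, pwm)
  plus <- hits[hits$strand == "+" & hits$spacer_class == 12, ]
  expect_equal(plus$hept_start, 200)
  expect_equal(plus$score, pwm$max_score)
  # reverse complement: same score on the minus strand, mirrored position
  hits_rc <- scan_rss(revcomp(s), pwm)
  minus <- hits_rc[hits_rc$strand == "-" & hits_rc$spacer_class == 12, ]
  expect_equal(minus$score, pwm$max_score)
  expect_equal(minus$hept_start, nchar(s) - 200 - 7)
  expect_error(scan_rss("ACGTACGT", pwm), "shorter")
})

test_that("both spacer-length variants within a class are found", {
  pwm <- rss_pwm()
  for (sp in c(11, 12, 13, 22, 23, 24)) {
    set.seed(sp)
    s <- paste0(random_dna(100), consensus_rss(sp), random_dna(100))
    hits <- scan_rss(s, pwm)
    cls <- if (sp <= 13) 12 else 23
    hit <- hits[hits$hept_start == 100 & hits$spacer_class == cls, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$spacer_len, sp)
    expect_equal(hit$score, pwm$max_score)
  }
})

test_that("scan_rss equals the independent full-window oracle", {
  pwm <- rss_pwm()
  set.seed(52)
  for (i in 1:10) {
    s <- random_dna(2000)
    # low threshold so random sequence yields hits to compare
    got <- scan_rss(s, pwm, threshold = 6)
    want <- oracle_scan_rss(s, pwm, threshold = 6)
    key <- function(d) paste(d$hept_start, d$strand, d$spacer_class,
                             d$spacer_len)
    o1 <- got[order(key(got)), ]
    o2 <- want[order(key(want)), ]
    expect_equal(nrow(o1), nrow(o2))
    expect_equal(key(o1), key(o2))
    expect_equal(o1$score, o2$score, tolerance = 1e-9)
  }
})

test_that("random sequence yields well under one hit per 10 kb", {
  set.seed(53)
  n_hits <- sum(vapply(1:10, function(i)
    nrow(scan_rss(random_dna(10000), rss_pwm())), numeric(1)))
  expect_lte(n_hits / 10, 1)
})

test_that("window edge semantics: one-base heptamer overlap counts", {
  set.seed(54)
  pwm <- rss_pwm()
  bg <- random_dna(2000)
  pos <- 1000
  plant_at <- function(start) {
    s <- bg
    substr(s, start + 1, start + 28) <- consensus_rss(12)
    s
  }
  sv_at <- function(genome_seq) {
    sv <- data.frame(sv_id = "s", chromA = "chr", posA = pos,
                     chromB = "chr", posB = pos + 600, insert_seq = "")
    annotate_breakpoint(sv, c(chr = genome_seq), window = 50, pwm = pwm)
  }
  # heptamer [1050, 1057): last base overlaps pos+50 (closed window)
  expect_true(sv_at(plant_at(pos + 44))$sideA_cRSS)
  expect_true(sv_at(plant_at(pos + 50))$sideA_cRSS)
  # one bp further: heptamer starts at pos+51, no overlap
  expect_false(sv_at(plant_at(pos + 51))$sideA_cRSS)
  # left edge: heptamer ending exactly at pos-50 still overlaps
  expect_true(sv_at(plant_at(pos - 50 - 6))$sideA_cRSS)
  expect_false(sv_at(plant_at(pos - 50 - 7))$sideA_cRSS)
})

test_that("SV types follow strand/insert rules", {
  g <- c(chr1 = paste0(strrep("A", 50), "CCCGGGTTT", strrep("A", 50)),
         chr9 = strrep("T", 100))
  del <- data.frame(chromA = "chr1", posA = 10, chromB = "chr1",
                    posB = 50, insert_seq = "")
  expect_equal(classify_sv_type(del), "deletion")
  tra <- data.frame(chromA = "chr1", posA = 10, chromB = "chr9",
                    posB = 50, insert_seq = "")
  expect_equal(classify_sv_type(tra), "translocation")
  ins <- data.frame(chromA = "chr1", posA = 10, chromB = "chr1",
                    posB = 10, insert_seq = "GTCGTCAGTACGATCA")
  expect_equal(classify_sv_type(ins, g), "insertion")
  cplx <- ins
  cplx$insert_seq <- "CCCGGGTTT"   # maps to a third location
  expect_equal(classify_sv_type(cplx, g), "complex_insertion")
  bad <- data.frame(chromA = NA, posA = 1, chromB = "chr1", posB = 2,
                    insert_seq = "")
  expect_error(classify_sv_type(bad), "malformed")
})

test_that("mechanism attribution recovers planted labels exactly", {
  svset <- simulate_sv_set(n_sv = 40, locus = fix_locus, seed = 55)
  ann <- annotate_sv_table(svset$svs, svset$genome,
                           loci_regions = svset$loci_regions)
  expect_equal(ann$category, svset$svs$category_truth)
  expect_equal(ann$mechanism, svset$svs$mechanism_truth)
  expect_equal(ann$sv_type, svset$svs$svtype_truth)
  # category booleans are consistent
  expect_equal(ann$category == "double", ann$sideA_cRSS & ann$sideB_cRSS)
  expect_equal(ann$category == "none", !ann$sideA_cRSS & !ann$sideB_cRSS)
  # reintegration only on insertion types
  expect_true(all(ann$sv_type[ann$mechanism == "reintegration"] %in%
                    c("insertion", "complex_insertion")))
})

test_that("gene-set enrichment uses the upper-tail hypergeometric", {
  genes <- data.frame(chrom = "bg1", start = (0:19) * 100,
                      end = (0:19) * 100 + 99,
                      gene = sprintf("G%02d", 1:20))
  universe <- genes$gene
  rset <- universe[1:5]
  mk <- function(posA, cat) {
    list(svs = data.frame(sv_id = seq_along(posA), chromA = "bg1",
                          posA = posA, chromB = "bg1", posB = posA,
                          insert_seq = ""),
         ann = data.frame(category = cat))
  }
  # population: 10 gene-mapped SVs, 4 of them in the relapse set;
  # draws: the 6 single-cRSS SVs, of which 4 fall in the set
  x <- mk(c(10, 110, 210, 310, 610, 710, 810, 910, 1010, 1110),
          rep(c("single", "none"), c(6, 4)))
  res <- gene_set_enrichment(x$ann, x$svs, genes, rset, universe)
  expect_equal(c(res$overlap, res$draws, res$successes_in_pop,
                 res$pop_size), c(4, 6, 4, 10))
  # oracle: exhaustive enumeration over all 6-subsets of the 10 SVs
  combos <- utils::combn(10, 6)
  p_oracle <- mean(apply(combos, 2, function(ix) sum(ix <= 4) >= 4))
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  # zero overlap -> upper tail at k = 0 is 1
  x0 <- mk(c(610, 710), rep("single", 2))
  expect_equal(gene_set_enrichment(x0$ann, x0$svs, genes, rset,
                                   universe)$p, 1)
  # set = universe, all draws inside -> p = 1
  xa <- mk(c(10, 110), rep("single", 2))
  expect_equal(gene_set_enrichment(xa$ann, xa$svs, genes, universe,
                                   universe)$p, 1)
  expect_error(gene_set_enrichment(xa$ann, xa$svs, genes, rset,
                                   character(0)), "universe|contained")
})
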