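# shared fixtures, built once per test run (all deterministic)

fix_locus <- build_locus(locus_config(seed = 7))
fix_db <- enumerate_junctions(fix_locus)

# wide-gap locus: junctions separated by more than the cluster merge
# distance, the geometry WGS detection assumes (real V segments sit tens
# of kb apart)
fix_wide_locus <- build_locus(locus_config(gap = 2500, seed = 7))
fix_wide_db <- enumerate_junctions(fix_wide_locus)

# larger locus for 20-junction LAM experiments
fix_big_locus <- build_locus(locus_config(n_v = 6, n_j = 4, seed = 7))
fix_big_db <- enumerate_junctions(fix_big_locus)

fix_loci_regions <- function(locus) {
  data.frame(chrom = locus$name, start = 0, end = nchar(locus$sequence))
}

# brute-force best-entry assignment: exhaustive Smith-Waterman (via
# Biostrings, an independent implementation) of the read against every db
# entry on both strands, same scoring scheme as the seeded aligner
# (match 2, mismatch -2, linear gap 3)
oracle_best_entry <- function(read, db) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                  mismatch = -2,
                                                  baseOnly = TRUE)
  refs <- Biostrings::DNAStringSet(c(db$ref_seq, revcomp(db$ref_seq)))
  sc <- Biostrings::pairwiseAlignment(
    refs, read, type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 3, scoreOnly = TRUE)
  per_entry <- pmax(sc[seq_len(nrow(db))],
                    sc[nrow(db) + seq_len(nrow(db))])
  best_score <- max(per_entry)
  winners <- unique(db$junction_id[per_entry >= best_score - 1e-9])
  list(junction_id = winners[1], score = best_score,
       tie = length(winners) > 1)
}

# independent full-window RSS scan using Biostrings PWM scoring
oracle_scan_rss <- function(sequence, pwm, threshold) {
  score_strand <- function(s) {
    subj <- Biostrings::DNAString(s)
    L <- nchar(s)
    Wh <- pwm$heptamer[1:4, ]
    Wn <- pwm$nonamer[1:4, ]
    nh <- L - 7 + 1
    nn <- L - 9 + 1
    hs <- Biostrings::PWMscoreStartingAt(Wh, subj, seq_len(nh))
    ns <- Biostrings::PWMscoreStartingAt(Wn, subj, seq_len(nn))
    list(hs = hs, ns = ns, L = L)
  }
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    sc <- score_strand(s)
    for (cls in c(12L, 23L)) {
      for (sp in (cls - 1L):(cls + 1L)) {
        off <- 7L + sp
        np <- min(length(sc$hs), length(sc$ns) - off)
        if (np < 1) next
        p <- seq_len(np)
        tot <- sc$hs[p] + sc$ns[p + off]
        hit <- p[tot >= threshold]
        if (length(hit)) {
          fwd <- if (strand == "+") hit - 1L else sc$L - (hit - 1L + 7L)
          out[[length(out) + 1L]] <- data.frame(
            hept_start = fwd, strand = strand, spacer_class = cls,
            spacer_len = sp, score = tot[hit])
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
    else data.frame(hept_start = integer(0), strand = character(0),
                    spacer_class = integer(0), spacer_len = integer(0),
                    score = numeric(0))
  if (nrow(res)) {
    res <- res[order(res$hept_start, res$strand, res$spacer_class,
                     -res$score), ]
    res <- res[!duplicated(res[, c("hept_start", "strand",
                                   "spacer_class")]), ]
    rownames(res) <- NULL
  }
  res
}

# exact Mann-Whitney p by full enumeration of group assignments
oracle_mwu_p <- function(a, b) {
  n <- length(a) + length(b)
  vals <- c(a, b)
  u_stat <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  }
  obs <- u_stat(seq_along(a))
  combos <- utils::combn(n, length(a))
  us <- apply(combos, 2, function(ix) {
    r <- rank(vals)
    sum(r[ix]) - length(a) * (length(a) + 1) / 2
  })
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# exact signed-rank p by enumeration over all sign assignments
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  ws <- as.matrix(signs) %*% r
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}
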