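#' Simulate WGS-style paired-end reads over a population
#'
#' Draws sequencing fragments from the (unrecombined) locus reference and
#' from every excised circle present in the population truth. Fragments
#' from a circle may span the signal joint; their read pairs then map back
#' to the reference in divergent (outward-facing) orientation, and a read
#' crossing the joint itself maps as a split read. Alignment records are
#' produced directly from the known simulation geometry (exact projection of
#' each fragment onto the reference), so the detector can be tested without
#' an external aligner.
#'
#' @param truth a [simulate_population()] result.
#' @param locus the `IgLocus` the population was simulated on.
#' @param cfg the [sim_config()] (fragment/read geometry, error rate, seed).
#' @param circle_coverage mean fragment coverage per circle with at least
#'   one copy (default 20).
#' @param genome_coverage mean read coverage of the background reference.
#' @return list with
#'   \describe{
#'     \item{alignments}{data.frame, one row per aligned read (or split-read
#'       part): `qname`, `rname`, `pos` (0-based), `end`, `strand`, `cigar`,
#'       `mate` (1/2), `supplementary`, `seq`.}
#'     \item{reads}{per-read truth: `qname`, `mate`, `origin` ("genome" or
#'       the event id), `spans_sj` (read crosses the joint), `frag_spans_sj`
#'       (fragment crosses the joint).}
#'   }
#' @export
simulate_wgs_reads <- function(truth, locus, cfg,
                               circle_coverage = 20, genome_coverage = 2) {
  stopifnot(inherits(truth, "population_truth"))
  rl <- cfg$wgs_read_len
  fmean <- cfg$wgs_fragment_mean
  if (fmean < 2 * rl) stopf("fragment mean < 2 x read length")
  set.seed(derive_seed(cfg$seed, "wgs"))
  gseq <- locus$sequence
  L <- nchar(gseq)
  aln <- list()
  reads <- list()
  frag_flag <- list()
  qn <- 0L

  add_read <- function(qname, mate, gstart, gend, strand, origin,
                       wrap_at = NA_integer_) {
    # wrap_at: circle boundary genome coords c(cs, ce) if the read crosses
    if (is.na(wrap_at[1])) {
      s <- substr0(gseq, gstart, gend)
      if (strand == "-") s <- revcomp(s)
      s <- mutate_seq(s, cfg$seq_error_rate)
      aln[[length(aln) + 1L]] <<- data.frame(
        qname = qname, rname = locus$name, pos = gstart, end = gend,
        strand = strand, cigar = sprintf("%dM", gend - gstart),
        mate = mate, supplementary = FALSE, seq = s)
      reads[[length(reads) + 1L]] <<- data.frame(
        qname = qname, mate = mate, origin = origin, spans_sj = FALSE)
    } else {
      cs <- wrap_at[1]; ce <- wrap_at[2]
      # read runs ... ce) then wraps to [cs ...: two blocks
      a_len <- gend  # here gstart..: block A = [gstart, ce), B = [cs, cs+b)
      a <- ce - gstart
      b <- (gend - gstart) - a
      blockA <- substr0(gseq, gstart, ce)
      blockB <- substr0(gseq, cs, cs + b)
      s <- paste0(blockA, blockB)          # read in circle + orientation
      if (strand == "-") s <- revcomp(s)
      s <- mutate_seq(s, cfg$seq_error_rate)
      primA <- a >= b
      cigA <- if (strand == "+") sprintf("%dM%dS", a, b)
              else sprintf("%dS%dM", b, a)
      cigB <- if (strand == "+") sprintf("%dS%dM", a, b)
              else sprintf("%dM%dS", b, a)
      aln[[length(aln) + 1L]] <<- data.frame(
        qname = qname, rname = locus$name,
        pos = c(gstart, cs), end = c(ce, cs + b),
        strand = strand, cigar = c(cigA, cigB),
        mate = mate, supplementary = c(!primA, primA), seq = s)
      reads[[length(reads) + 1L]] <<- data.frame(
        qname = qname, mate = mate, origin = origin, spans_sj = TRUE)
    }
  }

  # background fragments from the linear reference
  n_bg <- ceiling(genome_coverage * L / (2 * rl))
  for (i in seq_len(n_bg)) {
    flen <- max(2L * rl + 10L, round(rnorm(1, fmean, cfg$wgs_fragment_sd)))
    if (flen >= L) flen <- L - 1L
    s0 <- sample.int(L - flen, 1L) - 1L
    qn <- qn + 1L
    qname <- sprintf("bg_%d", qn)
    add_read(qname, 1L, s0, s0 + rl, "+", "genome")
    add_read(qname, 2L, s0 + flen - rl, s0 + flen, "-", "genome")
  }

  # circle fragments per event with surviving copies
  tot <- truth$totals[truth$totals$sj_copies > 0, , drop = FALSE]
  db <- truth$db
  for (k in seq_len(nrow(tot))) {
    ent <- db[db$junction_id == tot$sj_id[k], ]
    cs <- ent$circle_start; ce <- ent$circle_end
    Lc <- ce - cs
    nf <- ceiling(circle_coverage * Lc / fmean)
    for (i in seq_len(nf)) {
      flen <- max(2L * rl + 10L,
                  round(rnorm(1, fmean, cfg$wgs_fragment_sd)))
      if (flen >= Lc) flen <- Lc - 1L
      s0 <- sample.int(Lc, 1L) - 1L   # circle offset
      qn <- qn + 1L
      qname <- sprintf("circ%d_%d", tot$event_id[k], qn)
      frag_wraps <- s0 + flen > Lc
      emit_circle_read <- function(mate, cstart, strand) {
        g1 <- cs + (cstart %% Lc)
        wraps <- cstart %% Lc + rl > Lc
        if (!wraps) add_read(qname, mate, g1, g1 + rl, strand,
                             tot$event_id[k])
        else add_read(qname, mate, g1, g1 + rl, strand, tot$event_id[k],
                      wrap_at = c(cs, ce))
        wraps
      }
      emit_circle_read(1L, s0, "+")
      emit_circle_read(2L, s0 + flen - rl, "-")
      frag_flag[[qname]] <- frag_wraps
    }
  }
  alignments <- do.call(rbind, aln)
  read_truth <- do.call(rbind, reads)
  ff <- unlist(frag_flag)
  read_truth$frag_spans_sj <- if (is.null(ff)) FALSE
    else !is.na(ff[read_truth$qname]) & ff[read_truth$qname]
  rownames(alignments) <- rownames(read_truth) <- NULL
  list(alignments = alignments, reads = read_truth)
}

#' Design a nested primer set for a locus
#'
#' One primer per downstream (J-side) partner and assay. Coding
#' (LAM-recombination) primers sit inside/downstream of the J segment (or
#' KDE) and read back across the coding junction on the minus strand.
#' Signal (LAM-ESC) primers sit in the circle's J-side flank upstream of the
#' joint and read forward across the signal joint.
#'
#' @param locus an `IgLocus`.
#' @param primer_len primer length in bp.
#' @param amplicon_len total amplicon length; the junction sits
#'   `amplicon_len/2` from the primed end.
#' @return data.frame of class `primer_set`: `primer_id`, `target`
#'   (downstream partner name), `assay` ("coding"/"signal"), `seq`.
#' @export
design_primers <- function(locus, primer_len = 20, amplicon_len = 320) {
  s <- locus$segments
  half <- amplicon_len %/% 2L
  rows <- list()
  for (i in which(s$kind %in% c("J", "KDE"))) {
    b <- s$boundary[i]
    cod <- revcomp(substr0(locus$sequence, b + half - primer_len, b + half))
    sig <- substr0(locus$sequence, b - half, b - half + primer_len)
    rows[[length(rows) + 1L]] <- data.frame(
      primer_id = paste0(s$name[i], "_coding"),
      target = s$name[i], assay = "coding", seq = cod)
    rows[[length(rows) + 1L]] <- data.frame(
      primer_id = paste0(s$name[i], "_signal"),
      target = s$name[i], assay = "signal", seq = sig)
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$seq)) stopf("primer sequences are not unique")
  class(out) <- c("primer_set", "data.frame")
  out
}

# amplicon sequence for one event/assay in read-1 orientation.
# Signal amplicons read forward across the joint on the circle; coding
# amplicons prime inside the downstream (J/KDE) side and read back across
# the coding junction, so read 1 is the reverse complement of the genomic
# junction region. For an inverted upstream segment the sequence 5' of
# the junction in the recombined chromosome is the reverse complement of
# the genomic window just downstream of the boundary.
lam_amplicon <- function(locus, db, event, assay, amplicon_len) {
  half <- amplicon_len %/% 2L
  ent <- db[db$junction_id ==
              (if (assay == "signal") event$sj_id else event$rec_id), ]
  if (nrow(ent) == 0) stopf("junction absent from database")
  gseq <- locus$sequence
  bu <- ent$boundary_up; bd <- ent$boundary_down
  if (assay == "signal") {
    if (ent$topology != "deletional")
      stopf("no signal amplicon for an inversional event")
    paste0(substr0(gseq, bd - half, bd), substr0(gseq, bu, bu + half))
  } else {
    vside <- if (isTRUE(ent$up_inverted)) revcomp(substr0(gseq, bu, bu + half))
             else substr0(gseq, bu - half, bu)
    revcomp(paste0(vside, event$insert_seq, substr0(gseq, bd, bd + half)))
  }
}

#' Simulate LAM amplicon read pairs
#'
#' Generates 2 x `lam_read_len` overlapping read pairs for one assay over
#' the population truth. `total_reads` reads are multinomially distributed
#' over events proportionally to copy number x a per-event lognormal
#' amplification efficiency (sd `lam_noise_sd`); each read 1 begins with
#' the J-side nested primer and crosses the junction; substitution errors
#' are applied at `seq_error_rate`.
#'
#' @param truth a [simulate_population()] result.
#' @param locus the `IgLocus`.
#' @param cfg the [sim_config()].
#' @param assay `"signal"` (LAM-ESC) or `"coding"` (LAM-recombination).
#' @param total_reads experiment sequencing depth (default 2000).
#' @return list with `r1`, `r2` (named character vectors; names are read
#'   ids) and `reads` (truth data.frame: `read_id`, `event_id`,
#'   `junction_id`, `assay`).
#' @export
simulate_lam_reads <- function(truth, locus, cfg,
                               assay = c("signal", "coding"),
                               total_reads = 2000) {
  assay <- match.arg(assay)
  tot <- truth$totals
  counts <- data.frame(
    junction_id = if (assay == "signal") tot$sj_id else tot$rec_id,
    event_id = tot$event_id,
    copies = if (assay == "signal") tot$sj_copies else tot$rec_copies,
    insert_seq = truth$events$insert_seq[match(tot$event_id,
                                               truth$events$event_id)])
  simulate_lam_reads_from_counts(locus, truth$db, counts, cfg, assay,
                                 total_reads)
}

#' Simulate LAM read pairs from explicit junction copy numbers
#'
#' Lower-level generator used by [simulate_lam_reads()] and by tests that
#' need junctions at chosen copy numbers.
#'
#' @param locus an `IgLocus`.
#' @param db its junction database.
#' @param counts data.frame `junction_id`, `copies` (and optionally
#'   `event_id`, `insert_seq` for coding junctions).
#' @param cfg a [sim_config()].
#' @param assay `"signal"` or `"coding"`.
#' @param total_reads experiment depth.
#' @return as [simulate_lam_reads()].
#' @export
simulate_lam_reads_from_counts <- function(locus, db, counts, cfg,
                                           assay = c("signal", "coding"),
                                           total_reads = 2000) {
  assay <- match.arg(assay)
  set.seed(derive_seed(cfg$seed, paste0("lam_", assay)))
  rl <- cfg$lam_read_len
  if (is.null(counts$event_id)) counts$event_id <- seq_len(nrow(counts))
  if (is.null(counts$insert_seq)) counts$insert_seq <- ""
  if (!all(counts$junction_id %in% db$junction_id))
    stopf("junction absent from database")
  keep <- counts$copies > 0
  counts <- counts[keep, , drop = FALSE]
  eff <- rlnorm(nrow(counts), 0, cfg$lam_noise_sd)
  w <- counts$copies * eff
  n_per <- if (nrow(counts)) drop(rmultinom(1, total_reads, w / sum(w)))
           else integer(0)
  r1 <- character(0); r2 <- character(0); tr <- list()
  for (k in seq_len(nrow(counts))) {
    n <- n_per[k]
    if (n == 0) next
    ent <- counts[k, ]
    event <- list(sj_id = ent$junction_id, rec_id = ent$junction_id,
                  insert_seq = ent$insert_seq)
    amp <- lam_amplicon(locus, db, event, assay, cfg$lam_amplicon_len)
    alen <- nchar(amp)
    ids <- sprintf("%s_e%s_%d", assay, ent$event_id, seq_len(n))
    s1 <- substr(amp, 1, min(rl, alen))
    s2 <- revcomp(substr(amp, max(1, alen - rl + 1), alen))
    new1 <- vapply(seq_len(n), function(i)
      mutate_seq(s1, cfg$seq_error_rate), character(1))
    new2 <- vapply(seq_len(n), function(i)
      mutate_seq(s2, cfg$seq_error_rate), character(1))
    r1[ids] <- new1
    r2[ids] <- new2
    tr[[length(tr) + 1L]] <- data.frame(
      read_id = ids, event_id = ent$event_id,
      junction_id = ent$junction_id, assay = assay)
  }
  list(r1 = r1, r2 = r2,
       reads = if (length(tr)) do.call(rbind, tr)
               else data.frame(read_id = character(0), event_id = integer(0),
                               junction_id = character(0),
                               assay = character(0)))
}
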