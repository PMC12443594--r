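#' Pair up alignment records
#'
#' Collapses a per-read alignment table (primary records only) into one row
#' per read pair, ordering mates by coordinate.
#'
#' @param alignments data.frame with `qname`, `rname`, `pos`, `end`,
#'   `strand`, `supplementary` columns (as produced by
#'   [simulate_wgs_reads()] or [read_sam()]).
#' @return data.frame with one row per qname: `qname`, `chrom1`, `start1`,
#'   `end1`, `strand1`, `chrom2`, `start2`, `end2`, `strand2` where mate 1
#'   is the leftmost (or the `chrom`-lexicographically first for
#'   interchromosomal pairs).
#' @export
build_pairs <- function(alignments) {
  a <- alignments[!alignments$supplementary, , drop = FALSE]
  sp <- split(a, a$qname)
  rows <- lapply(sp, function(d) {
    if (nrow(d) != 2) return(NULL)
    o <- order(d$rname, d$pos)
    d <- d[o, ]
    data.frame(qname = d$qname[1],
               chrom1 = d$rname[1], start1 = d$pos[1], end1 = d$end[1],
               strand1 = d$strand[1],
               chrom2 = d$rname[2], start2 = d$pos[2], end2 = d$end[2],
               strand2 = d$strand[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a read pair's mapping geometry
#'
#' The signal-joint (circle junction) signature is the *divergent* pair:
#' mates face outward, each pointing away from the other -- the geometry a
#' fragment spanning a circular junction produces when mapped to the linear
#' reference. Inward-facing pairs with an insert within `mean +/- k*sd` are
#' concordant; inward pairs outside that range are `convergent_distal`
#' (e.g. deletion-spanning); equal strands are `same_strand`; different
#' chromosomes `interchrom`.
#'
#' @param pairs a [build_pairs()] table.
#' @param insert_mean,insert_sd expected insert size distribution.
#' @param k concordance width in sds (default 4).
#' @return factor of classes, one per pair.
#' @export
classify_pair <- function(pairs, insert_mean, insert_sd, k = 4) {
  lv <- c("concordant", "divergent", "convergent_distal", "same_strand",
          "interchrom")
  cls <- character(nrow(pairs))
  inter <- pairs$chrom1 != pairs$chrom2
  same <- !inter & pairs$strand1 == pairs$strand2
  inward <- !inter & !same & pairs$strand1 == "+" & pairs$strand2 == "-"
  outward <- !inter & !same & pairs$strand1 == "-" & pairs$strand2 == "+"
  insert <- pairs$end2 - pairs$start1
  conc <- inward & abs(insert - insert_mean) <= k * insert_sd
  cls[inter] <- "interchrom"
  cls[same] <- "same_strand"
  cls[outward] <- "divergent"
  cls[inward & conc] <- "concordant"
  cls[inward & !conc] <- "convergent_distal"
  factor(cls, levels = lv)
}

in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    pos >= regions$start[i] & pos < regions$end[i])
  }
  hit
}

#' Detect signal-joint candidates from divergent read pairs
#'
#' Keeps divergent pairs whose mates both fall inside the supplied
#' antigen-receptor regions, estimates per pair the circle boundaries (the
#' outward-facing left mate starts at or right of the circle start; the
#' right mate ends at or left of the circle end), clusters pairs whose
#' boundary estimates agree within `merge_distance`, and drops clusters
#' below `min_support`. Candidates are optionally matched to signal entries
#' of a junction database by breakpoint proximity.
#'
#' @param pairs a [build_pairs()] table (or alignments; coerced).
#' @param loci_regions data.frame `chrom`, `start`, `end` (0-based
#'   half-open) of antigen receptor loci.
#' @param insert_mean,insert_sd expected insert distribution for
#'   [classify_pair()].
#' @param db optional `junction_db`; signal entries are matched by
#'   proximity of both breakpoints within `match_tolerance`.
#' @param min_support minimum supporting pairs+split reads (default 2).
#' @param merge_distance cluster merge distance in bp (default 1000).
#' @param match_tolerance db matching tolerance in bp for exactly
#'   resolved candidates (default 10).
#' @param interval_match_tolerance db matching tolerance for candidates
#'   without split-read support, whose boundary estimates carry
#'   fragment-scale uncertainty (default 200).
#' @return data.frame of class `sj_candidates`: `chrom`, `posA`, `posB`
#'   (candidate circle start/end), `support_divergent_pairs`,
#'   `support_split_reads`, `breakpoint_resolution`, `matched_db_entry`.
#' @export
detect_sj_candidates <- function(pairs, loci_regions,
                                 insert_mean = 500, insert_sd = 60,
                                 db = NULL, min_support = 2,
                                 merge_distance = 1000,
                                 match_tolerance = 10,
                                 interval_match_tolerance = 200) {
  if (is.null(loci_regions) || nrow(loci_regions) == 0)
    stopf("empty loci region set")
  if (!"chrom1" %in% names(pairs)) pairs <- build_pairs(pairs)
  cls <- classify_pair(pairs, insert_mean, insert_sd)
  dv <- pairs[cls == "divergent", , drop = FALSE]
  keep <- in_regions(dv$chrom1, dv$start1, loci_regions) &
    in_regions(dv$chrom2, dv$start2, loci_regions)
  dv <- dv[keep, , drop = FALSE]
  empty <- data.frame(chrom = character(0), posA = integer(0),
                      posB = integer(0),
                      support_divergent_pairs = integer(0),
                      support_split_reads = integer(0),
                      breakpoint_resolution = character(0),
                      matched_db_entry = character(0))
  class(empty) <- c("sj_candidates", "data.frame")
  if (nrow(dv) == 0) return(empty)
  # per-pair boundary estimates: left (minus-strand) mate start ~ circle
  # start from above; right (plus-strand) mate end ~ circle end from below
  dv$estA <- dv$start1
  dv$estB <- dv$end2
  dv <- dv[order(dv$chrom1, dv$estA, dv$estB), ]
  # greedy 2-d clustering: a pair joins the first open cluster whose
  # running (A, B) centroids both lie within merge_distance
  cl_id <- integer(nrow(dv))
  cA <- numeric(0); cB <- numeric(0); cn <- integer(0); cc <- character(0)
  for (i in seq_len(nrow(dv))) {
    hit <- which(cc == dv$chrom1[i] &
                   abs(cA / cn - dv$estA[i]) <= merge_distance &
                   abs(cB / cn - dv$estB[i]) <= merge_distance)
    if (length(hit)) {
      j <- hit[1]
      cA[j] <- cA[j] + dv$estA[i]
      cB[j] <- cB[j] + dv$estB[i]
      cn[j] <- cn[j] + 1L
    } else {
      cA <- c(cA, dv$estA[i]); cB <- c(cB, dv$estB[i])
      cn <- c(cn, 1L); cc <- c(cc, dv$chrom1[i])
      j <- length(cn)
    }
    cl_id[i] <- j
  }
  cand <- do.call(rbind, lapply(split(dv, cl_id), function(d) data.frame(
    chrom = d$chrom1[1],
    posA = min(d$estA), posB = max(d$estB),
    support_divergent_pairs = nrow(d),
    support_split_reads = 0L,
    breakpoint_resolution = "interval",
    matched_db_entry = NA_character_)))
  cand <- cand[cand$support_divergent_pairs >= min_support, , drop = FALSE]
  rownames(cand) <- NULL
  if (!is.null(db) && nrow(cand)) {
    cand$matched_db_entry <- match_candidates_db(cand, db, match_tolerance,
                                                 interval_match_tolerance)
  }
  class(cand) <- c("sj_candidates", "data.frame")
  cand
}

match_candidates_db <- function(cand, db, match_tolerance,
                                interval_match_tolerance = 200) {
  sig <- db[db$kind == "signal" & db$topology == "deletional", ]
  vapply(seq_len(nrow(cand)), function(i) {
    tol <- if (cand$breakpoint_resolution[i] == "exact") match_tolerance
           else interval_match_tolerance
    dA <- abs(sig$circle_start - cand$posA[i])
    dB <- abs(sig$circle_end - cand$posB[i])
    ok <- which(dA <= tol & dB <= tol)
    if (length(ok) == 0) return(NA_character_)
    sig$junction_id[ok[which.min(dA[ok] + dB[ok])]]
  }, character(1))
}

#' Extract split-read junction observations from alignments
#'
#' A split read has a primary and a supplementary record whose matched
#' blocks abut the two sides of a circle junction: the block ending at the
#' circle end and the block starting at the circle start. Each such read
#' votes for one exact `(posA, posB)` junction.
#'
#' @param alignments alignment table including supplementary records.
#' @return data.frame `qname`, `chrom`, `posA` (circle start), `posB`
#'   (circle end), one row per split read.
#' @export
split_read_junctions <- function(alignments) {
  spl <- alignments$qname[alignments$supplementary]
  a <- alignments[alignments$qname %in% spl, , drop = FALSE]
  key <- paste(a$qname, a$mate)
  rows <- lapply(split(a, key), function(d) {
    if (nrow(d) != 2) return(NULL)
    d <- d[order(d$pos), ]
    # left part [cs, cs+b), right part [x, ce): junction joins ce -> cs
    data.frame(qname = d$qname[1], chrom = d$rname[1],
               posA = d$pos[1], posB = d$end[2])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(qname = character(0), chrom = character(0),
                      posA = integer(0), posB = integer(0))
  rownames(out) <- NULL
  out
}

#' Refine a candidate with split reads
#'
#' If at least one split read's two blocks abut the candidate breakpoints
#' (within `merge_distance`), the candidate becomes exactly resolved at the
#' majority-vote coordinates (ties broken towards the lower coordinate
#' pair).
#'
#' @param candidate one-row `sj_candidates` data.frame.
#' @param splits a [split_read_junctions()] table.
#' @param merge_distance how far a split read may sit from the candidate's
#'   interval estimate and still count (default 1000).
#' @return the candidate row, possibly with `posA`/`posB` replaced,
#'   `support_split_reads` set and `breakpoint_resolution = "exact"`.
#' @export
refine_with_split_reads <- function(candidate, splits,
                                    merge_distance = 1000) {
  s <- splits[splits$chrom == candidate$chrom &
                abs(splits$posA - candidate$posA) <= merge_distance &
                abs(splits$posB - candidate$posB) <= merge_distance, ,
              drop = FALSE]
  if (nrow(s) == 0) return(candidate)
  key <- paste(s$posA, s$posB)
  tab <- table(key)
  best <- names(tab)[tab == max(tab)]
  # tie-break: lowest coordinate pair
  pick <- best[order(as.integer(sub(" .*", "", best)),
                     as.integer(sub(".* ", "", best)))][1]
  pq <- as.integer(strsplit(pick, " ")[[1]])
  candidate$posA <- pq[1]
  candidate$posB <- pq[2]
  candidate$support_split_reads <- max(tab)
  candidate$breakpoint_resolution <- "exact"
  candidate
}

#' Full WGS signal-joint detection
#'
#' Convenience wrapper: pairs alignments, detects divergent-pair candidate
#' clusters within the loci regions, refines each with split reads, and
#' (re)matches against the junction database.
#'
#' @inheritParams detect_sj_candidates
#' @param alignments alignment table (with supplementary records).
#' @return `sj_candidates` table.
#' @export
detect_sj <- function(alignments, loci_regions, insert_mean = 500,
                      insert_sd = 60, db = NULL, min_support = 2,
                      merge_distance = 1000, match_tolerance = 10,
                      interval_match_tolerance = 200) {
  pairs <- build_pairs(alignments)
  cand <- detect_sj_candidates(pairs, loci_regions, insert_mean, insert_sd,
                               db = NULL, min_support = min_support,
                               merge_distance = merge_distance)
  if (nrow(cand)) {
    splits <- split_read_junctions(alignments)
    cand <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
      refine_with_split_reads(cand[i, ], splits, merge_distance)))
    cand$support_split_reads <- as.integer(cand$support_split_reads)
    if (!is.null(db))
      cand$matched_db_entry <- match_candidates_db(cand, db, match_tolerance,
                                                   interval_match_tolerance)
  }
  class(cand) <- c("sj_candidates", "data.frame")
  cand
}
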