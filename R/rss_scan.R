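#' Position-weight matrices for RSS heptamer/nonamer scanning
#'
#' Builds log-odds PWMs seeded from the canonical consensus motifs with a
#' tunable consensus probability (remaining mass spread over the other
#' bases) against a uniform background. External matrices (e.g. derived
#' from curated RSS collections) can be plugged in anywhere a `pwm_config`
#' is accepted, as a list with `heptamer` and `nonamer` matrices (rows
#' A,C,G,T,N; log2 odds).
#'
#' @param heptamer,nonamer consensus motifs.
#' @param consensus_prob probability mass on the consensus base per
#'   position (default 0.79, roughly the conservation of the canonical
#'   heptamer/nonamer cores).
#' @return list of class `pwm_config` with `heptamer`, `nonamer` score
#'   matrices and `max_score`.
#' @export
rss_pwm <- function(heptamer = "CACAGTG", nonamer = "ACAAAAACC",
                    consensus_prob = 0.79) {
  mk <- function(motif) {
    ch <- strsplit(motif, "", fixed = TRUE)[[1]]
    m <- matrix(log2(((1 - consensus_prob) / 3) / 0.25),
                nrow = 5, ncol = length(ch),
                dimnames = list(c("A", "C", "G", "T", "N"), NULL))
    for (j in seq_along(ch)) m[ch[j], j] <- log2(consensus_prob / 0.25)
    m["N", ] <- 0  # ambiguous base scores as background
    m
  }
  h <- mk(heptamer); n <- mk(nonamer)
  structure(list(heptamer = h, nonamer = n,
                 max_score = sum(apply(h, 2, max)) + sum(apply(n, 2, max))),
            class = "pwm_config")
}

# rolling PWM score vector: score[i] = sum_j W[base[i+j-1], j]
pwm_scores <- function(base_idx, W) {
  L <- length(base_idx)
  w <- ncol(W)
  if (L < w) return(numeric(0))
  n <- L - w + 1L
  s <- numeric(n)
  for (j in seq_len(w)) {
    s <- s + W[cbind(base_idx[j:(j + n - 1L)], j)]
  }
  s
}

#' Scan a sequence for cryptic RSS motifs
#'
#' Both strands are scanned; for each heptamer position, the nonamer is
#' scored at spacer offsets `class - 1`, `class` and `class + 1` for both
#' spacer classes (the 12 +/- 1 / 23 +/- 1 bp definition), and the best
#' combined heptamer+nonamer log-odds per (position, strand, class) at or
#' above `threshold` is reported.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param pwm a [rss_pwm()] config.
#' @param threshold minimum combined log2-odds score (default 15,
#'   calibrated so the consensus scores maximally and random sequence
#'   yields well under one hit per 10 kb).
#' @return data.frame of class `rss_hits`: `hept_start` (0-based, on the
#'   forward strand, i.e. leftmost base of the heptamer's genomic
#'   footprint), `strand`, `spacer_class`, `spacer_len`, `score`, sorted
#'   by position.
#' @export
scan_rss <- function(sequence, pwm = rss_pwm(), threshold = 15) {
  L <- nchar(sequence)
  if (L < 7 + 11 + 9) stopf("sequence shorter than the minimal RSS span")
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    idx <- match(strsplit(s, "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T"))
    idx[is.na(idx)] <- 5L
    hs <- pwm_scores(idx, pwm$heptamer)
    ns <- pwm_scores(idx, pwm$nonamer)
    nh <- length(hs)
    for (cls in c(12L, 23L)) {
      for (sp in (cls - 1L):(cls + 1L)) {
        off <- 7L + sp              # nonamer start offset from heptamer
        valid <- seq_len(max(0L, min(nh, length(ns) - off)))
        if (!length(valid)) next
        tot <- hs[valid] + ns[valid + off]
        hit <- which(tot >= threshold)
        if (length(hit)) {
          # map scan-strand heptamer start to forward-strand coordinates
          p <- hit - 1L
          fwd <- if (strand == "+") p else L - (p + 7L)
          res[[length(res) + 1L]] <- data.frame(
            hept_start = fwd, strand = strand, spacer_class = cls,
            spacer_len = sp, score = tot[hit])
        }
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res)
    else data.frame(hept_start = integer(0), strand = character(0),
                    spacer_class = integer(0), spacer_len = integer(0),
                    score = numeric(0))
  # best spacer variant per (position, strand, class)
  if (nrow(out)) {
    out <- out[order(out$hept_start, out$strand, out$spacer_class,
                     -out$score), ]
    out <- out[!duplicated(out[, c("hept_start", "strand",
                                   "spacer_class")]), ]
    rownames(out) <- NULL
  }
  class(out) <- c("rss_hits", "data.frame")
  out
}

#' Classify a structural variant by its breakpoint strands and insert
#'
#' Same-chromosome co-linear loss is a deletion; different chromosomes a
#' translocation; novel sequence between the ends an insertion, upgraded
#' to a complex insertion when the insert itself maps elsewhere in the
#' genome (on either strand).
#'
#' @param sv one-row data.frame with `chromA`, `posA`, `chromB`, `posB`,
#'   `insert_seq` (empty string for none).
#' @param genome named character vector of chromosome sequences (used to
#'   locate inserts; optional -- without it inserted sequence yields
#'   "insertion").
#' @return one of `"deletion"`, `"insertion"`, `"complex_insertion"`,
#'   `"translocation"`.
#' @export
classify_sv_type <- function(sv, genome = NULL) {
  if (is.na(sv$chromA) || is.na(sv$chromB)) stopf("malformed SV record")
  ins <- sv$insert_seq
  if (!is.na(ins) && nzchar(ins)) {
    if (!is.null(genome) && insert_maps_to(ins, genome))
      return("complex_insertion")
    return("insertion")
  }
  if (sv$chromA != sv$chromB) return("translocation")
  "deletion"
}

insert_maps_to <- function(ins, genome, regions = NULL) {
  for (chrom in names(genome)) {
    hitf <- gregexpr(ins, genome[[chrom]], fixed = TRUE)[[1]]
    hitr <- gregexpr(revcomp(ins), genome[[chrom]], fixed = TRUE)[[1]]
    pos <- c(if (hitf[1] != -1L) hitf - 1L, if (hitr[1] != -1L) hitr - 1L)
    if (!length(pos)) next
    if (is.null(regions)) return(TRUE)
    if (any(in_regions(rep(chrom, length(pos)), pos, regions)))
      return(TRUE)
  }
  FALSE
}

#' Annotate an SV breakpoint pair with cryptic-RSS sidedness
#'
#' Scans a window of `window` bp either side of each breakpoint; a side
#' carries a cRSS when at least one RSS hit's heptamer overlaps the closed
#' window `[pos - window, pos + window]` by at least one base. Breakpoints
#' falling inside configured antigen-receptor loci are flagged (such SVs
#' are omitted from cohort tallies).
#'
#' @param sv one-row SV data.frame (`sv_id`, `chromA`, `posA`, `chromB`,
#'   `posB`, `insert_seq`).
#' @param genome named character vector of chromosome sequences.
#' @param window bp either side of each breakpoint (default 50).
#' @param pwm,threshold scanner settings (see [scan_rss()]).
#' @param loci_regions optional antigen-receptor regions data.frame.
#' @return one-row data.frame of class `breakpoint_annotation`: `sv_id`,
#'   `sv_type`, `sideA_cRSS`, `sideB_cRSS`, `category`
#'   (none/single/double), `in_antigen_receptor_locus`.
#' @export
annotate_breakpoint <- function(sv, genome, window = 50, pwm = rss_pwm(),
                                threshold = 15, loci_regions = NULL) {
  side_hit <- function(chrom, pos) {
    gl <- nchar(genome[[chrom]])
    if (is.null(genome[[chrom]]) || pos < 0 || pos >= gl)
      stopf("breakpoint outside genome")
    lo <- max(0, pos - window - 30)       # margin so edge motifs score
    hi <- min(gl, pos + window + 30 + 16 + 24)
    hits <- scan_rss(substr0(genome[[chrom]], lo, hi), pwm, threshold)
    if (nrow(hits) == 0) return(FALSE)
    hs <- hits$hept_start + lo
    he <- hs + 7L - 1L                     # heptamer last base
    any(he >= pos - window & hs <= pos + window)
  }
  a <- side_hit(sv$chromA, sv$posA)
  b <- side_hit(sv$chromB, sv$posB)
  category <- c("none", "single", "double")[1L + a + b]
  in_ar <- FALSE
  if (!is.null(loci_regions)) {
    in_ar <- any(in_regions(c(sv$chromA, sv$chromB), c(sv$posA, sv$posB),
                            loci_regions))
  }
  out <- data.frame(sv_id = sv$sv_id,
                    sv_type = classify_sv_type(sv, genome),
                    sideA_cRSS = a, sideB_cRSS = b, category = category,
                    in_antigen_receptor_locus = in_ar)
  class(out) <- c("breakpoint_annotation", "data.frame")
  out
}

#' Attribute a likely mechanism to an annotated SV
#'
#' Rules, in order: an insertion whose insert originates from the antigen
#' receptor loci is circle reintegration; a double-cRSS SV is off-target
#' recombination between two cRSSs; an insertion near a single cRSS with a
#' non-immune insert is a RAG-mediated insertion; any other single-cRSS SV
#' is a cut-and-run candidate; everything else `other`.
#'
#' @param annotation a [annotate_breakpoint()] row.
#' @param insert_seq the SV's inserted sequence ("" if none).
#' @param genome named chromosome sequences.
#' @param loci_regions antigen-receptor regions data.frame.
#' @return mechanism string.
#' @export
attribute_mechanism <- function(annotation, insert_seq, genome,
                                loci_regions) {
  is_ins <- annotation$sv_type %in% c("insertion", "complex_insertion")
  ins_ig <- is_ins && nzchar(insert_seq) &&
    insert_maps_to(insert_seq, genome, loci_regions)
  if (ins_ig) return("reintegration")
  if (annotation$category == "double") return("two_cRSS_offtarget")
  if (annotation$category == "single") {
    if (is_ins) return("rag_insertion")
    return("cut_and_run_candidate")
  }
  "other"
}

#' Annotate and mechanism-classify a full SV table
#'
#' @param svs SV data.frame (`sv_id`, `chromA`, `posA`, `chromB`, `posB`,
#'   `insert_seq`).
#' @inheritParams annotate_breakpoint
#' @return data.frame with annotation columns plus `mechanism`.
#' @export
annotate_sv_table <- function(svs, genome, window = 50, pwm = rss_pwm(),
                              threshold = 15, loci_regions = NULL) {
  rows <- lapply(seq_len(nrow(svs)), function(i) {
    ann <- annotate_breakpoint(svs[i, ], genome, window, pwm, threshold,
                               loci_regions)
    ann$mechanism <- attribute_mechanism(ann, svs$insert_seq[i], genome,
                                         loci_regions)
    ann
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-set enrichment of single-cRSS SVs
#'
#' Maps annotated SVs to genes by breakpoint-interval overlap, then tests
#' whether single-cRSS SVs hit the relapse-associated gene set more often
#' than expected under a one-sided (upper-tail) hypergeometric null:
#' population = all gene-mapped SVs, successes = those in the gene set,
#' draws = the single-cRSS SVs.
#'
#' @param annotations a [annotate_sv_table()] result.
#' @param svs the matching SV table (for coordinates).
#' @param gene_intervals data.frame `chrom`, `start`, `end`, `gene`.
#' @param relapse_gene_set character vector of gene names (subset of the
#'   universe).
#' @param universe character vector of all gene names considered.
#' @return list `overlap` (k), `draws` (n), `successes_in_pop` (K),
#'   `pop_size` (N), `p` (upper-tail hypergeometric).
#' @export
gene_set_enrichment <- function(annotations, svs, gene_intervals,
                                relapse_gene_set, universe) {
  if (length(universe) == 0) stopf("empty gene universe")
  if (!all(relapse_gene_set %in% universe))
    stopf("relapse gene set must be contained in the universe")
  sv_gene <- vapply(seq_len(nrow(svs)), function(i) {
    g <- gene_intervals$gene[
      (gene_intervals$chrom == svs$chromA[i] &
         svs$posA[i] >= gene_intervals$start &
         svs$posA[i] < gene_intervals$end) |
      (gene_intervals$chrom == svs$chromB[i] &
         svs$posB[i] >= gene_intervals$start &
         svs$posB[i] < gene_intervals$end)]
    if (length(g)) g[1] else NA_character_
  }, character(1))
  mapped <- !is.na(sv_gene) & sv_gene %in% universe
  N <- sum(mapped)
  K <- sum(mapped & sv_gene %in% relapse_gene_set)
  single <- annotations$category == "single"
  n <- sum(mapped & single)
  k <- sum(mapped & single & sv_gene %in% relapse_gene_set)
  p <- if (n == 0 || N == 0) 1 else hypergeometric_upper(k, K, n, N)
  list(overlap = k, draws = n, successes_in_pop = K, pop_size = N, p = p)
}
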