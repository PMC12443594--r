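#' Toy antigen-receptor locus configuration
#'
#' Describes a configurable immunoglobulin-light-chain-style locus: a set of
#' V gene segments (each flanked 3' by a 12-RSS), J gene segments (each
#' flanked 5' by a 23-RSS), an optional intronic RSS and kappa-deleting
#' element (KDE), and a constant-region exon. RSS orientations are chosen so
#' that V-to-J and V/intron-to-KDE joins are deletional (heptamers
#' convergent) unless a V is explicitly flipped to inversional orientation.
#'
#' Coordinates are 0-based half-open throughout, BED-compatible.
#'
#' @param name locus name (also the FASTA sequence name).
#' @param n_v,n_j number of V and J gene segments.
#' @param v_orientation character vector of length `n_v`, each
#'   `"deletional"` or `"inversional"`.
#' @param kde include a kappa-deleting element plus intronic RSS.
#' @param v_spacer,j_spacer,intron_spacer,kde_spacer RSS spacer classes;
#'   recombination follows the 12/23 rule so V/intron take class 12 and
#'   J/KDE class 23 by default.
#' @param v_gene_len,j_gene_len,const_len,gap segment and inter-segment
#'   lengths in bp.
#' @param heptamer,nonamer consensus RSS motifs used when synthesising RSSs.
#' @param alleles allele count per cell (default 2).
#' @param seed integer seed for the random background sequence.
#' @return a list of class `locus_config`.
#' @export
locus_config <- function(name = "igtoy", n_v = 3, n_j = 2,
                         v_orientation = rep("deletional", n_v),
                         kde = TRUE,
                         v_spacer = 12, j_spacer = 23,
                         intron_spacer = 12, kde_spacer = 23,
                         v_gene_len = 120, j_gene_len = 60,
                         const_len = 200, gap = 400,
                         heptamer = "CACAGTG", nonamer = "ACAAAAACC",
                         alleles = 2, seed = 1) {
  stopifnot(n_v >= 1, n_j >= 1, nchar(heptamer) == 7, nchar(nonamer) == 9)
  v_orientation <- match.arg(v_orientation,
                             c("deletional", "inversional"), several.ok = TRUE)
  v_orientation <- rep_len(v_orientation, n_v)
  if (!all(c(v_spacer, intron_spacer) %in% c(12, 23)) ||
      !all(c(j_spacer, kde_spacer) %in% c(12, 23)))
    stopf("spacer classes must be 12 or 23")
  structure(list(name = name, n_v = n_v, n_j = n_j,
                 v_orientation = v_orientation, kde = kde,
                 v_spacer = v_spacer, j_spacer = j_spacer,
                 intron_spacer = intron_spacer, kde_spacer = kde_spacer,
                 v_gene_len = v_gene_len, j_gene_len = j_gene_len,
                 const_len = const_len, gap = gap,
                 heptamer = heptamer, nonamer = nonamer,
                 alleles = alleles, seed = seed),
            class = "locus_config")
}

# one RSS unit as a genomic (+ strand) string.
# strand "+": heptamer..spacer..nonamer left to right (motif points downstream)
# strand "-": revcomp(nonamer)..spacer..revcomp(heptamer) (points upstream)
rss_unit <- function(heptamer, nonamer, spacer_len, strand) {
  sp <- random_dna(spacer_len)
  if (strand == "+") paste0(heptamer, sp, nonamer)
  else paste0(revcomp(nonamer), sp, revcomp(heptamer))
}

#' Build a toy immunoglobulin locus
#'
#' Assembles the locus sequence from a [locus_config()]: random intergenic
#' background with gene segments and their RSSs embedded at recorded
#' coordinates. Deterministic for a fixed config seed.
#'
#' The segment table records, per segment: its interval, the RSS heptamer
#' start (`hept_start`), the RSS strand (`"+"` points downstream, `"-"`
#' upstream), spacer class/length, and the cleavage `boundary` between gene
#' segment and heptamer (for a `"+"` RSS the heptamer start; for a `"-"` RSS
#' the heptamer end), which is the coordinate arithmetic anchor for every
#' junction in the package.
#'
#' @param config a [locus_config()].
#' @return object of class `IgLocus`: list with `name`, `sequence`,
#'   `segments` (data.frame), `alleles` and the originating `config`.
#' @export
build_locus <- function(config) {
  stopifnot(inherits(config, "locus_config"))
  set.seed(config$seed)
  cfg <- config
  parts <- character(0)
  segs <- list()
  pos <- 0L
  emit <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  emit(random_dna(cfg$gap))
  # V segments
  for (i in seq_len(cfg$n_v)) {
    nm <- paste0("V", i)
    sp <- cfg$v_spacer
    unit_gene <- random_dna(cfg$v_gene_len)
    if (cfg$v_orientation[i] == "deletional") {
      g0 <- pos
      emit(unit_gene)
      h0 <- pos
      emit(rss_unit(cfg$heptamer, cfg$nonamer, sp, "+"))
      segs[[length(segs) + 1L]] <- data.frame(
        name = nm, kind = "V", start = g0, end = g0 + cfg$v_gene_len,
        strand = "+", hept_start = h0, spacer_class = sp, spacer_len = sp,
        rss_strand = "+", boundary = h0)
    } else {
      # inverted V unit: RSS (pointing upstream-to-gene, i.e. "-") then gene
      r0 <- pos
      emit(rss_unit(cfg$heptamer, cfg$nonamer, sp, "-"))
      g0 <- pos
      emit(revcomp(unit_gene))
      segs[[length(segs) + 1L]] <- data.frame(
        name = nm, kind = "V", start = g0, end = g0 + cfg$v_gene_len,
        strand = "-", hept_start = r0 + 9L + sp, spacer_class = sp,
        spacer_len = sp, rss_strand = "-", boundary = r0 + 16L + sp)
    }
    emit(random_dna(cfg$gap))
  }
  # J segments: RSS upstream pointing "-" (heptamer abuts gene start)
  for (i in seq_len(cfg$n_j)) {
    nm <- paste0("J", i)
    sp <- cfg$j_spacer
    r0 <- pos
    emit(rss_unit(cfg$heptamer, cfg$nonamer, sp, "-"))
    g0 <- pos
    emit(random_dna(cfg$j_gene_len))
    segs[[length(segs) + 1L]] <- data.frame(
      name = nm, kind = "J", start = g0, end = g0 + cfg$j_gene_len,
      strand = "+", hept_start = g0 - 7L, spacer_class = sp, spacer_len = sp,
      rss_strand = "-", boundary = g0)
    emit(random_dna(cfg$gap))
  }
  if (cfg$kde) {
    # intronic RSS pointing downstream towards KDE
    i0 <- pos
    sp <- cfg$intron_spacer
    emit(rss_unit(cfg$heptamer, cfg$nonamer, sp, "+"))
    segs[[length(segs) + 1L]] <- data.frame(
      name = "intronRSS", kind = "intronRSS", start = i0,
      end = i0 + 16L + sp, strand = "+", hept_start = i0,
      spacer_class = sp, spacer_len = sp, rss_strand = "+", boundary = i0)
    emit(random_dna(cfg$gap))
  }
  c0 <- pos
  emit(random_dna(cfg$const_len))
  segs[[length(segs) + 1L]] <- data.frame(
    name = "C", kind = "constant", start = c0, end = c0 + cfg$const_len,
    strand = "+", hept_start = NA_integer_, spacer_class = NA_integer_,
    spacer_len = NA_integer_, rss_strand = NA_character_,
    boundary = NA_integer_)
  emit(random_dna(cfg$gap))
  if (cfg$kde) {
    k0 <- pos
    sp <- cfg$kde_spacer
    emit(rss_unit(cfg$heptamer, cfg$nonamer, sp, "-"))
    segs[[length(segs) + 1L]] <- data.frame(
      name = "KDE", kind = "KDE", start = k0, end = k0 + 16L + sp,
      strand = "+", hept_start = k0 + 9L + sp, spacer_class = sp,
      spacer_len = sp, rss_strand = "-", boundary = k0 + 16L + sp)
    emit(random_dna(cfg$gap))
  }
  segments <- do.call(rbind, segs)
  locus <- structure(list(name = cfg$name,
                          sequence = paste(parts, collapse = ""),
                          segments = segments,
                          alleles = cfg$alleles,
                          config = cfg),
                     class = "IgLocus")
  validate_locus(locus)
  locus
}

#' Validate an IgLocus
#'
#' Checks the structural invariants: segment intervals within the sequence
#' and non-overlapping, V/J segments carrying exactly one RSS, at most one
#' KDE, and each recorded heptamer/nonamer actually present in the sequence
#' at its coordinates.
#'
#' @param locus an `IgLocus`.
#' @return the locus, invisibly; errors on violation.
#' @export
validate_locus <- function(locus) {
  s <- locus$segments
  L <- nchar(locus$sequence)
  if (any(s$start < 0 | s$end > L | s$start >= s$end))
    stopf("segment interval outside [0, %d)", L)
  o <- order(s$start)
  if (any(s$end[o][-nrow(s)] > s$start[o][-1]))
    stopf("overlapping segment intervals")
  if (any(s$kind %in% c("V", "J") & is.na(s$hept_start)))
    stopf("V/J segment without an RSS")
  if (sum(s$kind == "KDE") > 1L)
    stopf("more than one KDE element")
  for (i in which(!is.na(s$hept_start))) {
    got <- rss_motifs_at(locus, s[i, ])
    if (got$heptamer != locus$config$heptamer ||
        got$nonamer != locus$config$nonamer)
      stopf("RSS motif mismatch at segment %s", s$name[i])
  }
  invisible(locus)
}

#' Extract the heptamer/nonamer recorded for a segment's RSS
#'
#' Reads the motifs back out of the locus sequence, on the RSS strand.
#'
#' @param locus an `IgLocus`.
#' @param seg one row of `locus$segments`.
#' @return list with `heptamer` and `nonamer` strings as read 5'->3' on the
#'   RSS strand.
#' @export
rss_motifs_at <- function(locus, seg) {
  h0 <- seg$hept_start
  sp <- seg$spacer_len
  if (seg$rss_strand == "+") {
    hept <- substr0(locus$sequence, h0, h0 + 7L)
    nona <- substr0(locus$sequence, h0 + 7L + sp, h0 + 16L + sp)
  } else {
    hept <- revcomp(substr0(locus$sequence, h0, h0 + 7L))
    nona <- revcomp(substr0(locus$sequence, h0 - sp - 9L, h0 - sp))
  }
  list(heptamer = hept, nonamer = nona)
}

get_segment <- function(locus, name) {
  i <- match(name, locus$segments$name)
  if (is.na(i)) stopf("no segment named '%s'", name)
  locus$segments[i, ]
}

#' Classify the topology of a candidate recombination
#'
#' A pair recombines deletionally when the two RSS heptamers face each other
#' in the genome (convergent orientation): joining them then excises the
#' intervening DNA as a circle carrying the signal joint. Any other mutual
#' orientation retains the signal joint in the chromosome (inversional).
#' Pairs violating the 12/23 rule (equal spacer classes) are rejected.
#'
#' @param locus an `IgLocus`.
#' @param a,b segment names (order irrelevant; sorted by coordinate).
#' @return `"deletional"` or `"inversional"`.
#' @export
classify_topology <- function(locus, a, b) {
  sa <- get_segment(locus, a)
  sb <- get_segment(locus, b)
  if (is.na(sa$hept_start) || is.na(sb$hept_start))
    stopf("both segments must carry an RSS")
  if (sa$spacer_class == sb$spacer_class)
    stopf("12/23 rule violation: %d/%d spacer pair",
          sa$spacer_class, sb$spacer_class)
  if (sa$start > sb$start) { tmp <- sa; sa <- sb; sb <- tmp }
  if (sa$rss_strand == "+" && sb$rss_strand == "-") "deletional"
  else "inversional"
}

# the recombining partner pairs of a locus: every V with every J,
# every V with KDE, and intronRSS with KDE. partner "up" is the
# upstream (V-side) segment, "down" the downstream (J-side) one.
locus_pairs <- function(locus) {
  s <- locus$segments
  vs <- s$name[s$kind == "V"]
  js <- s$name[s$kind == "J"]
  pairs <- expand.grid(up = vs, down = js, stringsAsFactors = FALSE)
  if ("KDE" %in% s$name) {
    pairs <- rbind(pairs,
                   data.frame(up = vs, down = "KDE"),
                   data.frame(up = "intronRSS", down = "KDE"))
  }
  pairs
}

#' Enumerate the junction reference database of a locus
#'
#' Builds the bespoke reference database used by both the LAM junction
#' caller and the WGS signal-joint detector: one coding (recombination
#' junction) entry per valid partner pair regardless of topology, and one
#' signal-joint entry per deletional pair only -- a signal joint from an
#' inversional event stays chromosomal and is excluded, as are all intra-V
#' ("intra-KV") joins, which never appear as pairs.
#'
#' Signal references are written J-side flank first (5'->3'), then the
#' V-side signal end, matching LAM-ESC priming from J regions; the two
#' heptamers meet head-to-head at `junction_offset`. Coding references are
#' V-gene flank then J-gene flank, joined at `junction_offset`.
#'
#' @param locus an `IgLocus`.
#' @param flank_len bp of reference on each side of the join (>= 20).
#' @return data.frame of class `junction_db` with columns `junction_id`,
#'   `kind` (coding/signal), `partnerA` (J-side), `partnerB` (V-side),
#'   `topology`, `circle_start`, `circle_end` (0-based half-open excised
#'   interval; NA for inversional), `junction_offset`, `flank_truncated`,
#'   `ref_seq`.
#' @export
enumerate_junctions <- function(locus, flank_len = 60) {
  if (flank_len < 20) stopf("flank_len must be >= 20")
  seq <- locus$sequence
  L <- nchar(seq)
  pairs <- locus_pairs(locus)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    up <- get_segment(locus, pairs$up[i])
    down <- get_segment(locus, pairs$down[i])
    topo <- classify_topology(locus, up$name, down$name)
    bu <- up$boundary
    bd <- down$boundary
    trunc <- FALSE
    if (topo == "deletional") {
      # circle = [bu, bd); coding join fuses bu-upstream to bd-downstream
      fu <- min(flank_len, bu)
      fd <- min(flank_len, L - bd)
      fin <- min(flank_len, bd - bu)  # flanks inside the circle
      trunc <- fu < flank_len || fd < flank_len || fin < flank_len
      coding <- paste0(substr0(seq, bu - fu, bu), substr0(seq, bd, bd + fd))
      signal <- paste0(substr0(seq, bd - fin, bd), substr0(seq, bu, bu + fin))
      rows[[length(rows) + 1L]] <- data.frame(
        junction_id = paste0("REC_", down$name, "_", up$name),
        kind = "coding", partnerA = down$name, partnerB = up$name,
        topology = topo, circle_start = bu, circle_end = bd,
        boundary_up = bu, boundary_down = bd, up_inverted = FALSE,
        junction_offset = fu, flank_truncated = trunc, ref_seq = coding)
      rows[[length(rows) + 1L]] <- data.frame(
        junction_id = paste0("SJ_", down$name, "_", up$name),
        kind = "signal", partnerA = down$name, partnerB = up$name,
        topology = topo, circle_start = bu, circle_end = bd,
        boundary_up = bu, boundary_down = bd, up_inverted = FALSE,
        junction_offset = fin, flank_truncated = trunc, ref_seq = signal)
    } else {
      # inversional: coding join = inverted upstream gene flank + downstream
      fu <- min(flank_len, up$end - bu)
      fd <- min(flank_len, L - bd)
      trunc <- fu < flank_len || fd < flank_len
      vflank <- if (up$strand == "-") revcomp(substr0(seq, bu, bu + fu))
                else substr0(seq, bu - fu, bu)
      coding <- paste0(vflank, substr0(seq, bd, bd + fd))
      rows[[length(rows) + 1L]] <- data.frame(
        junction_id = paste0("REC_", down$name, "_", up$name),
        kind = "coding", partnerA = down$name, partnerB = up$name,
        topology = topo, circle_start = NA_integer_,
        circle_end = NA_integer_, boundary_up = bu, boundary_down = bd,
        up_inverted = up$strand == "-", junction_offset = fu,
        flank_truncated = trunc, ref_seq = coding)
    }
  }
  db <- do.call(rbind, rows)
  rownames(db) <- NULL
  class(db) <- c("junction_db", "data.frame")
  db
}

#' Reconstruct the unrecombined allele from a deletional junction
#'
#' For a deletional pair, the coding join plus the excised circle partition
#' the locus: pasting sequence upstream of the circle, the circle itself and
#' the downstream remainder reproduces the allele exactly. Used as a
#' structural self-check.
#'
#' @param locus an `IgLocus`.
#' @param db_entry one signal or coding row of a [enumerate_junctions()] db.
#' @return the reconstructed locus sequence (character scalar).
#' @export
reconstruct_allele <- function(locus, db_entry) {
  stopifnot(db_entry$topology == "deletional")
  seq <- locus$sequence
  paste0(substr0(seq, 0, db_entry$circle_start),
         substr0(seq, db_entry$circle_start, db_entry$circle_end),
         substr0(seq, db_entry$circle_end, nchar(seq)))
}

#' @export
print.IgLocus <- function(x, ...) {
  cat(sprintf("IgLocus '%s': %d bp, %d segments, %d allele(s)\n",
              x$name, nchar(x$sequence), nrow(x$segments), x$alleles))
  print(x$segments[, c("name", "kind", "start", "end", "strand",
                       "spacer_class", "rss_strand")])
  invisible(x)
}
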