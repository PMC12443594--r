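# hamming distance between equal-length prefixes
prefix_mismatches <- function(reads, primer) {
  pl <- nchar(primer)
  pv <- strsplit(primer, "", fixed = TRUE)[[1]]
  vapply(reads, function(r) {
    if (nchar(r) < pl) return(pl + 1L)
    sum(strsplit(substr(r, 1, pl), "", fixed = TRUE)[[1]] != pv)
  }, integer(1), USE.NAMES = FALSE)
}

#' Demultiplex reads by nested primer prefix
#'
#' Assigns each read 1 to the unique primer whose sequence matches its 5'
#' end within `max_mismatch` substitutions. Reads matching no primer, or
#' tying between two or more equally good primers, go to the `unassigned`
#' bin, so bin sizes plus unassigned always sum to the input count.
#'
#' @param r1 named character vector of read-1 sequences.
#' @param primers a [design_primers()] table (or any data.frame with
#'   `primer_id` and `seq`).
#' @param max_mismatch maximum substitutions tolerated (default 1).
#' @return list with `bins` (named list of read-id vectors per primer_id)
#'   and `unassigned` (read ids).
#' @export
demultiplex <- function(r1, primers, max_mismatch = 1) {
  if (anyDuplicated(primers$primer_id)) stopf("duplicate primer ids")
  mm <- sapply(primers$seq, function(p) prefix_mismatches(r1, p))
  mm <- matrix(mm, nrow = length(r1))
  best <- apply(mm, 1, min)
  nbest <- rowSums(mm == best)
  which_best <- apply(mm, 1, which.min)
  ok <- best <= max_mismatch & nbest == 1L
  ids <- names(r1)
  bins <- lapply(seq_len(nrow(primers)), function(j) ids[ok & which_best == j])
  names(bins) <- primers$primer_id
  list(bins = bins, unassigned = ids[!ok])
}

#' Merge a read pair by 3' overlap
#'
#' Scans every ungapped overlap of read 1's 3' end with the reverse
#' complement of read 2's 5' end (exhaustive shift enumeration), keeps the
#' overlap with the most matching bases subject to `min_overlap` and
#' `max_mismatch_rate`, and returns the merged sequence of length
#' `len1 + len2 - overlap`. Disagreeing bases within the overlap are taken
#' from the higher-quality read, read 1 winning ties. If no admissible
#' overlap exists, read 1 alone is returned with `merged = FALSE`.
#'
#' @param r1,r2 read sequences (read 2 in sequencing orientation; it is
#'   reverse-complemented internally).
#' @param q1,q2 optional integer quality vectors (per base).
#' @param min_overlap minimum overlap length (default 20).
#' @param max_mismatch_rate maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return list `seq`, `merged` (logical), `overlap` (bp, 0 if unmerged).
#' @export
merge_pair <- function(r1, r2, q1 = NULL, q2 = NULL, min_overlap = 20,
                       max_mismatch_rate = 0.1) {
  a <- strsplit(r1, "", fixed = TRUE)[[1]]
  b <- strsplit(revcomp1(r2), "", fixed = TRUE)[[1]]
  n1 <- length(a); n2 <- length(b)
  best_o <- 0L; best_m <- -1L
  for (o in seq(min(n1, n2), min_overlap)) {
    if (o <= best_m) break  # even a perfect shorter overlap cannot win
    mism <- sum(a[(n1 - o + 1):n1] != b[1:o])
    if (mism / o <= max_mismatch_rate && (o - mism) > best_m) {
      best_m <- o - mism; best_o <- o
    }
  }
  if (best_o == 0L)
    return(list(seq = r1, merged = FALSE, overlap = 0L))
  o <- best_o
  ov_a <- a[(n1 - o + 1):n1]
  ov_b <- b[1:o]
  ov <- ov_a
  diff <- which(ov_a != ov_b)
  if (length(diff)) {
    qa <- if (is.null(q1)) rep(30L, n1) else q1
    qb <- if (is.null(q2)) rep(30L, n2) else rev(q2)
    use_b <- qb[diff] > qa[(n1 - o) + diff]
    ov[diff[use_b]] <- ov_b[use_b]
  }
  merged <- paste0(paste(a[seq_len(n1 - o)], collapse = ""),
                   paste(ov, collapse = ""),
                   paste(b[(o + 1):n2][seq_len(max(0, n2 - o))],
                         collapse = ""))
  list(seq = merged, merged = TRUE, overlap = o)
}

#' Merge many pairs, falling back to read 1
#'
#' @param r1,r2 named character vectors (parallel).
#' @inheritParams merge_pair
#' @return data.frame `read_id`, `seq`, `merged`.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20, max_mismatch_rate = 0.1) {
  out <- lapply(seq_along(r1), function(i)
    merge_pair(r1[[i]], r2[[i]], min_overlap = min_overlap,
               max_mismatch_rate = max_mismatch_rate))
  data.frame(read_id = names(r1),
             seq = vapply(out, `[[`, character(1), "seq"),
             merged = vapply(out, `[[`, logical(1), "merged"))
}

# k-mer seed index over db entries (both strands). Each env entry maps a
# k-mer to an integer matrix with columns (entry, strand_code, ref_pos):
# strand_code 1 = "+", 2 = "-"; ref_pos 0-based on the indexed strand.
build_seed_index <- function(db, k = 12) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  add <- function(seqs, entry, strand_code) {
    n <- nchar(seqs)
    if (n < k) return()
    starts <- seq_len(n - k + 1L)
    kms <- substring(seqs, starts, starts + k - 1L)
    for (p in seq_along(kms)) {
      row <- c(entry, strand_code, p - 1L)
      km <- kms[p]
      idx[[km]] <- rbind(idx[[km]], row, deparse.level = 0)
    }
  }
  ref_rc <- revcomp(db$ref_seq)
  for (i in seq_len(nrow(db))) {
    add(db$ref_seq[i], i, 1L)
    add(ref_rc[i], i, 2L)
  }
  attr(idx, "k") <- k
  attr(idx, "ref_rc") <- ref_rc
  idx
}

#' Assign a read to a junction database entry
#'
#' Seeded, banded local alignment: candidate entries (and strands) are
#' those sharing at least one `k`-mer with the read; each candidate is
#' aligned with a banded Smith-Waterman (match 2, mismatch -2, linear gap
#' 3) around the seed diagonal. The best-scoring entry is reported if the
#' alignment identity is at least `min_identity` over a reference span of
#' at least `min_span` bp that crosses the junction point; equal top scores
#' on different entries yield `unassigned` (status "ambiguous").
#'
#' @param read a single read sequence (merged or read 1).
#' @param db a `junction_db` (any subset).
#' @param index optional precomputed [build_seed_index()]; pass when
#'   assigning many reads.
#' @param k seed k-mer length (default 12).
#' @param min_identity minimum alignment identity (default 0.9).
#' @param min_span minimum reference span (default 50).
#' @param band DP band half-width around the seed diagonal (default 32).
#' @param seed_step stride between sampled read k-mers (default 4; 1
#'   samples every position).
#' @param seed_frac candidates with fewer than `seed_frac` times the top
#'   candidate's seed count are not aligned (default 0.5; 0 disables the
#'   filter and aligns every seeded candidate).
#' @return list `junction_id` (or NA), `status`
#'   ("assigned"/"unassigned"/"ambiguous"), `identity`, `score`,
#'   `ref_span`.
#' @export
assign_junction <- function(read, db, index = NULL, k = 12,
                            min_identity = 0.9, min_span = 50, band = 32,
                            seed_step = 4, seed_frac = 0.5) {
  if (nrow(db) == 0) stopf("empty junction database")
  if (is.null(index)) index <- build_seed_index(db, k)
  n <- nchar(read)
  none <- list(junction_id = NA_character_, status = "unassigned",
               identity = NA_real_, score = NA_real_, ref_span = NA_real_)
  if (n < k) return(none)
  k <- attr(index, "k")
  starts <- seq.int(1L, n - k + 1L, by = seed_step)
  kmers <- substring(read, starts, starts + k - 1L)
  hits <- vector("list", length(kmers))
  for (i in seq_along(kmers)) {
    h <- index[[kmers[i]]]
    if (!is.null(h)) hits[[i]] <- cbind(h, starts[i] - 1L,
                                        deparse.level = 0)
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) return(none)
  # columns: entry, strand_code, ref_pos, read_pos
  key <- hits[, 1] * 2L + hits[, 2]
  # candidate filter: entries sharing only a flank with the read carry far
  # fewer seeds than the best entry; align the well-seeded ones only
  tab <- table(key)
  keep_keys <- as.integer(names(tab)[tab >= max(2, seed_frac * max(tab))])
  best <- NULL; best_score <- -Inf; tie <- FALSE
  for (ky in keep_keys) {
    h <- hits[key == ky, , drop = FALSE]
    e <- h[1, 1]
    strand <- if (h[1, 2] == 1L) "+" else "-"
    ref <- if (strand == "+") db$ref_seq[e] else attr(index, "ref_rc")[e]
    diag <- h[, 3] - h[, 4]
    d0 <- as.integer(names(sort(table(diag), decreasing = TRUE))[1])
    aln <- sw_banded(read, ref, d0, band)
    if (aln$score > best_score) {
      best_score <- aln$score; tie <- FALSE
      best <- c(aln, list(entry = e, strand = strand, ref = ref))
    } else if (aln$score == best_score && !is.null(best) &&
               e != best$entry) {
      tie <- TRUE
    }
  }
  if (is.null(best) || best_score <= 0) return(none)
  if (tie) {
    none$status <- "ambiguous"
    return(none)
  }
  identity <- best$matches / max(1L, best$aln_len)
  ref_span <- best$ref_end - best$ref_start
  # junction position on the aligned strand
  e <- best$entry
  jpos <- if (best$strand == "+") db$junction_offset[e]
          else nchar(db$ref_seq[e]) - db$junction_offset[e]
  crosses <- best$ref_start < jpos && best$ref_end > jpos
  if (identity >= min_identity && ref_span >= min_span && crosses) {
    list(junction_id = db$junction_id[e], status = "assigned",
         identity = identity, score = best_score, ref_span = ref_span)
  } else none
}

#' Assign many reads
#'
#' @param reads named character vector (or [merge_pairs()] data.frame).
#' @inheritParams assign_junction
#' @return data.frame `read_id`, `junction_id`, `status`, `identity`,
#'   `ref_span`.
#' @export
assign_junctions <- function(reads, db, k = 12, min_identity = 0.9,
                             min_span = 50, band = 32, seed_step = 4,
                             seed_frac = 0.5) {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$read_id)
  index <- build_seed_index(db, k)
  rows <- lapply(seq_along(reads), function(i) {
    a <- assign_junction(reads[[i]], db, index, k, min_identity, min_span,
                         band, seed_step, seed_frac)
    data.frame(read_id = names(reads)[i], junction_id = a$junction_id,
               status = a$status, identity = a$identity,
               ref_span = a$ref_span)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantify junctions in one experiment
#'
#' Raw read counts per junction, normalized by the total number of reads of
#' that assay in the experiment -- by default including unassigned reads,
#' matching normalization against total assay reads; set
#' `denominator = "assigned"` to normalize within assigned reads only.
#'
#' @param assignments an [assign_junctions()] table.
#' @param experiment_id experiment label.
#' @param assay assay label ("signal"/"coding").
#' @param total_reads total reads in the experiment for this assay
#'   (defaults to `nrow(assignments)`; pass explicitly when assignment was
#'   run on a demultiplexed subset).
#' @param denominator `"all"` (default) or `"assigned"`.
#' @return data.frame of class `junction_quant`: `junction_id`,
#'   `raw_reads`, `normalized_reads`, `above_threshold` (NA until
#'   [apply_threshold()]), `experiment_id`, `assay`.
#' @export
quantify <- function(assignments, experiment_id, assay,
                     total_reads = nrow(assignments),
                     denominator = c("all", "assigned")) {
  denominator <- match.arg(denominator)
  asn <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (total_reads == 0) stopf("zero total reads")
  denom <- if (denominator == "all") total_reads else max(1L, nrow(asn))
  tab <- table(asn$junction_id)
  out <- data.frame(junction_id = names(tab),
                    raw_reads = as.integer(tab),
                    normalized_reads = as.numeric(tab) / denom,
                    above_threshold = NA,
                    experiment_id = experiment_id, assay = assay)
  rownames(out) <- NULL
  class(out) <- c("junction_quant", "data.frame")
  out
}

#' Fit the control-derived detection threshold
#'
#' The threshold is the highest normalized junction level observed across
#' all control (healthy) experiments; sample junctions count as positive
#' only when strictly above it, so the controls themselves define zero
#' positives by construction.
#'
#' @param control_tables list of [quantify()] tables from control samples.
#' @return list of class `threshold_model`: `threshold`,
#'   `source_controls`.
#' @export
fit_threshold <- function(control_tables) {
  if (length(control_tables) == 0) stopf("no control tables")
  vals <- unlist(lapply(control_tables, `[[`, "normalized_reads"))
  ids <- unique(unlist(lapply(control_tables, function(t)
    unique(t$experiment_id))))
  structure(list(threshold = max(vals), source_controls = ids),
            class = "threshold_model")
}

#' Apply a threshold model to a quantification table
#'
#' @param table a [quantify()] table.
#' @param model a [fit_threshold()] model.
#' @return the table with `above_threshold` set (strict `>`).
#' @export
apply_threshold <- function(table, model) {
  table$above_threshold <- table$normalized_reads > model$threshold
  table
}

#' Run the full LAM calling pipeline on simulated reads
#'
#' demultiplex -> merge -> assign -> quantify, for one assay.
#'
#' @param r1,r2 named read vectors.
#' @param db junction database restricted as desired (e.g. signal entries
#'   only for LAM-ESC).
#' @param primers [design_primers()] table.
#' @param experiment_id,assay labels for [quantify()].
#' @param max_mismatch demultiplex mismatch tolerance.
#' @param ... passed to [assign_junctions()].
#' @return list `quant` (junction_quant), `assignments`, `demux` (bin
#'   stats), `merged` (merge table).
#' @export
lam_call <- function(r1, r2, db, primers, experiment_id, assay,
                     max_mismatch = 1, ...) {
  prim <- primers[primers$assay == assay, , drop = FALSE]
  dmx <- demultiplex(r1, prim, max_mismatch)
  keep <- unlist(dmx$bins, use.names = FALSE)
  mg <- merge_pairs(r1[keep], r2[keep])
  asn <- assign_junctions(mg, db, ...)
  quant <- quantify(asn, experiment_id, assay, total_reads = length(r1))
  list(quant = quant, assignments = asn,
       demux = list(bin_sizes = lengths(dmx$bins),
                    unassigned = length(dmx$unassigned)),
       merged = mg)
}
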