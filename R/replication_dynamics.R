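#' Estimate cell divisions from population doublings
#'
#' Inverts the population doubling formula `N2 = N1 * 2^n`:
#' `n = log2(N2/N1)`. Divisions may be fractional; no rounding is applied.
#'
#' @param N2 final copy (cell) count.
#' @param N1 initial cell count (default 1).
#' @return list of class `division_estimate`: `N1`, `N2`, `n`.
#' @export
estimate_divisions <- function(N2, N1 = 1) {
  if (any(N2 <= 0) || any(N1 <= 0)) stopf("N1 and N2 must be positive")
  structure(list(N1 = N1, N2 = N2, n = log2(N2 / N1)),
            class = "division_estimate")
}

#' Predicted signal-joint level under pure dilution
#'
#' Exponential decay of a non-replicating circle through `t` divisions:
#' `xt = x0 / 2^t`.
#'
#' @param x0 initial SJ copies (default 1).
#' @param t divisions since the recombination event (>= 0, may be
#'   fractional).
#' @return list of class `dilution_prediction`: `x0`, `t`, `xt`.
#' @export
predicted_sj <- function(x0 = 1, t) {
  if (any(t < 0)) stopf("t must be non-negative")
  structure(list(x0 = x0, t = t, xt = x0 / 2^t),
            class = "dilution_prediction")
}

#' Conservative predicted SJ sum over distinguishable clonotypes
#'
#' When the measured SJ could stem from any of several minor clonotypes of
#' the same junction, the conservative prediction sums the per-clonotype
#' dilution predictions `x0/2^t` over all of them.
#'
#' @param clonotype_divisions numeric vector of per-clonotype division
#'   estimates `t`.
#' @param x0 initial SJ copies per clonotype (default 1).
#' @return the summed predicted SJ level.
#' @export
conservative_predicted_sum <- function(clonotype_divisions, x0 = 1) {
  sum(predicted_sj(x0, clonotype_divisions)$xt)
}

#' Observed over predicted SJ ratio
#'
#' Under pure dilution the ratio sits at 1; values above 1 indicate
#' replication and/or persistence beyond what dilution allows.
#'
#' @param observed_sj observed SJ level.
#' @param predicted_sj predicted SJ level (> 0).
#' @return the ratio.
#' @export
observed_over_predicted <- function(observed_sj, predicted_sj) {
  if (any(predicted_sj <= 0)) stopf("predicted SJ level must be positive")
  observed_sj / predicted_sj
}

#' Select very recent recombination events
#'
#' Recent events are those whose coding junction has accumulated few reads:
#' normalized LAM-recombination reads at or below `cutoff` (inclusive).
#'
#' @param rec_table a [quantify()] table from the coding assay.
#' @param cutoff inclusive threshold on normalized reads (default 0.2).
#' @return the subset of rows.
#' @export
select_recent_events <- function(rec_table, cutoff = 0.2) {
  rec_table[rec_table$normalized_reads <= cutoff, , drop = FALSE]
}

#' Partition junctions into major and other recombination events
#'
#' Junctions are sorted by normalized recombination reads (descending); the
#' knee is the maximal drop of the discrete gradient
#' `g_i = y_i - y_{i+1}` (ties towards the smallest index). Junctions at or
#' before the knee are `major` -- recombination events many cell divisions
#' ago, carried by a large cell fraction. A single junction is major by
#' convention; on a strictly uniform distribution the knee falls at index 1
#' (one major).
#'
#' @param rec_table a [quantify()] table (coding assay).
#' @param scale `"linear"` (default) or `"log"` gradient scale.
#' @return list of class `major_event_partition`: `table` (sorted, with
#'   `label` major/other), `knee_index`.
#' @export
detect_major_events <- function(rec_table, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (nrow(rec_table) == 0) stopf("empty quantification table")
  tb <- rec_table[order(-rec_table$normalized_reads), , drop = FALSE]
  rownames(tb) <- NULL
  if (nrow(tb) == 1) {
    tb$label <- "major"
    return(structure(list(table = tb, knee_index = 1L),
                     class = "major_event_partition"))
  }
  y <- tb$normalized_reads
  if (scale == "log") y <- log10(pmax(y, .Machine$double.xmin))
  g <- y[-length(y)] - y[-1]
  knee <- which.max(g)  # ties -> smallest index
  tb$label <- ifelse(seq_len(nrow(tb)) <= knee, "major", "other")
  structure(list(table = tb, knee_index = as.integer(knee)),
            class = "major_event_partition")
}

#' Extract clonotypes from merged coding-junction reads
#'
#' Two 5-bp anchor motifs are taken from the reference flanks, each
#' starting 25 bp from the nominal (unprocessed) V-J boundary -- i.e. 5 bp
#' of reference followed by 20 bp omitted up to the boundary on the V side,
#' and 20 bp omitted then 5 bp of reference on the J side. Reads containing
#' both anchors exactly once yield the intervening sequence; identical
#' intervening sequences collapse to one clonotype (exact string identity).
#' Reads lacking an anchor, or where an anchor is non-unique, are discarded
#' and counted.
#'
#' @param merged_reads character vector of merged reads (any orientation;
#'   the reverse complement is tried when the anchors are not found).
#' @param v_ref reference sequence ending at the V-side boundary (>= 25
#'   bp).
#' @param j_ref reference sequence starting at the J-side boundary (>= 25
#'   bp).
#' @param anchor_len,omit_len anchor geometry (defaults 5 and 20).
#' @return list of class `clonotype_table`: `clonotypes` (data.frame
#'   `v_insert_j`, `read_count`, `fraction`), `n_discarded_missing`,
#'   `n_discarded_ambiguous`.
#' @export
extract_clonotypes <- function(merged_reads, v_ref, j_ref, anchor_len = 5,
                               omit_len = 20) {
  need <- anchor_len + omit_len
  if (nchar(v_ref) < need || nchar(j_ref) < need)
    stopf("references must provide >= %d bp flanking the boundary", need)
  va <- substr(v_ref, nchar(v_ref) - need + 1, nchar(v_ref) - omit_len)
  ja <- substr(j_ref, omit_len + 1, need)
  n_missing <- 0L; n_ambig <- 0L
  inserts <- character(0)
  for (rd in merged_reads) {
    got <- locate_anchors(rd, va, ja)
    if (is.null(got)) {
      got <- locate_anchors(revcomp(rd), va, ja)
    }
    if (is.null(got)) { n_missing <- n_missing + 1L; next }
    if (identical(got, "ambiguous")) { n_ambig <- n_ambig + 1L; next }
    inserts <- c(inserts, got)
  }
  tab <- sort(table(inserts), decreasing = TRUE)
  cl <- data.frame(v_insert_j = names(tab), read_count = as.integer(tab),
                   fraction = as.integer(tab) / max(1L, sum(tab)))
  rownames(cl) <- NULL
  structure(list(clonotypes = cl, n_discarded_missing = n_missing,
                 n_discarded_ambiguous = n_ambig),
            class = "clonotype_table")
}

locate_anchors <- function(rd, va, ja) {
  pv <- gregexpr(va, rd, fixed = TRUE)[[1]]
  pj <- gregexpr(ja, rd, fixed = TRUE)[[1]]
  if (pv[1] == -1L || pj[1] == -1L) return(NULL)
  if (length(pv) > 1L || length(pj) > 1L) return("ambiguous")
  if (pj <= pv) return(NULL)
  substr(rd, pv + nchar(va), pj - 1L)
}

#' Per-clonotype division estimates
#'
#' Converts clonotype fractions into cell-division estimates: each
#' clonotype's recombination copies are `absolute_event_copies x fraction`;
#' one recombination copy equates to one cell harbouring the recombination
#' (a single allele per event), so `n = log2(copies)`.
#'
#' @param clonotypes the `clonotypes` data.frame of a
#'   [extract_clonotypes()] result.
#' @param absolute_event_copies absolute copy number of the recombination
#'   event (ddPCR stand-in; > 0).
#' @return the data.frame with `copies` and `divisions` columns added.
#' @export
clonotype_division_profile <- function(clonotypes, absolute_event_copies) {
  if (absolute_event_copies <= 0) stopf("absolute copies must be positive")
  if (any(clonotypes$fraction < 0 | clonotypes$fraction > 1))
    stopf("fractions outside [0, 1]")
  clonotypes$copies <- absolute_event_copies * clonotypes$fraction
  clonotypes$divisions <- estimate_divisions(clonotypes$copies)$n
  clonotypes
}

#' Observed/predicted replication ratios from a population truth
#'
#' For every event: the observed per-cell SJ level is total surviving SJ
#' copies divided by carrier cells; the predicted level under pure dilution
#' is `1/2^t` from the division count implied by the recombination
#' footprint (`t = log2(rec copies)`). Their ratio is 1 in expectation
#' without replication and grows as `(1+r)^t` with replication probability
#' `r`.
#'
#' @param truth a [simulate_population()] result.
#' @param max_divisions optional paper-mode filter: keep only events with
#'   `t <= max_divisions` (the <= 6 relative divisions rule); `Inf`
#'   disables.
#' @param measurement `"exact"` uses truth copy numbers; `"poisson"` draws
#'   the observed SJ count from a Poisson around the truth (ddPCR-style
#'   counting noise).
#' @return data.frame `event_id`, `sj_id`, `t`, `observed`, `predicted`,
#'   `ratio`.
#' @export
replication_ratios <- function(truth, max_divisions = Inf,
                               measurement = c("exact", "poisson")) {
  measurement <- match.arg(measurement)
  tt <- truth$totals
  t_est <- log2(pmax(1, tt$rec_copies))
  obs_total <- if (measurement == "poisson") rpois(nrow(tt), tt$sj_copies)
               else tt$sj_copies
  observed <- obs_total / tt$rec_copies
  predicted <- predicted_sj(1, t_est)$xt
  out <- data.frame(event_id = tt$event_id, sj_id = tt$sj_id, t = t_est,
                    observed = observed, predicted = predicted,
                    ratio = observed_over_predicted(observed, predicted))
  out[out$t <= max_divisions, , drop = FALSE]
}
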