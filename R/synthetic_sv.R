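#' Simulate a structural-variant set with planted cryptic RSSs
#'
#' Builds a small synthetic genome (two background chromosomes plus the
#' antigen-receptor toy locus as its own chromosome) and an SV table in
#' which cryptic RSS motifs are planted within `window` bp of zero, one or
#' both breakpoint sides at exactly the configured proportions (allocation
#' is deterministic per record, largest-remainder rounding). Breakpoints of
#' `none`-class records are drawn only at positions whose windows are free
#' of chance hits at the scanner threshold, so planted class labels are
#' exact ground truth.
#'
#' Mechanism labels cycle deterministically within each class:
#' single-cRSS records alternate cut-and-run (deletion), cut-and-run
#' (translocation), reintegration (insert copied from the Ig locus) and
#' RAG-mediated insertion (random insert); double-cRSS records alternate
#' deletion/translocation off-target events; `none` records are plain
#' deletions labelled `other`.
#'
#' @param n_sv number of SV records.
#' @param proportions named numeric (none, single, double), summing to 1.
#' @param locus an `IgLocus` supplying the antigen-receptor chromosome and
#'   reintegration insert sequence.
#' @param bg_len background chromosome length (two chromosomes).
#' @param window cRSS planting window (bp, default 50).
#' @param pwm,threshold scanner settings used to vet `none` windows;
#'   planted motifs are consensus heptamer/nonamer pairs (random spacer)
#'   and score above any sensible threshold.
#' @param seed integer seed.
#' @return list with `svs` (data.frame `sv_id`, `chromA`, `posA`,
#'   `chromB`, `posB`, `svtype_truth`, `insert_seq`, `category_truth`,
#'   `mechanism_truth`), `genome` (named character vector) and
#'   `loci_regions` (antigen-receptor regions).
#' @export
simulate_sv_set <- function(n_sv = 60,
                            proportions = c(none = 0.5, single = 0.35,
                                            double = 0.15),
                            locus, bg_len = 30000, window = 50,
                            pwm = rss_pwm(), threshold = 15, seed = 1) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stopf("class proportions must sum to 1")
  stopifnot(all(c("none", "single", "double") %in% names(proportions)))
  set.seed(derive_seed(seed, "svset"))
  genome <- c(bg1 = random_dna(bg_len), bg2 = random_dna(bg_len))
  genome["igtoy_sv"] <- locus$sequence
  loci_regions <- data.frame(chrom = "igtoy_sv", start = 0,
                             end = nchar(locus$sequence))

  # largest-remainder allocation of class counts
  raw <- proportions * n_sv
  cnt <- floor(raw)
  rem <- n_sv - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  classes <- rep(c("none", "single", "double"),
                 times = cnt[c("none", "single", "double")])

  # positions whose +/- (window + motif) neighbourhood is hit-free
  clean_positions <- function(chrom, n_needed) {
    hits <- scan_rss(genome[[chrom]], pwm, threshold)
    bad <- unlist(lapply(hits$hept_start, function(h)
      (h - window - 7):(h + window + 7)))
    pool <- setdiff(seq(200, nchar(genome[[chrom]]) - 200, by = 190), bad)
    if (length(pool) < n_needed) stopf("background too crowded with hits")
    sample(pool, n_needed)
  }
  poolA <- sort(clean_positions("bg1", 2L * n_sv))
  posA1 <- poolA[seq(1L, 2L * n_sv, by = 2L)]
  posA2 <- poolA[seq(2L, 2L * n_sv, by = 2L)]  # same-chrom partner anchors
  posBg2 <- clean_positions("bg2", n_sv)

  motif_len <- 7 + 12 + 9
  plant <- function(chrom, pos, i) {
    # consensus 12-RSS planted so the heptamer overlaps [pos-w, pos+w]
    motif <- paste0("CACAGTG", random_dna(12), "ACAAAAACC")
    off <- (i %% (2 * window - 10)) - (window - 5)
    start <- pos + off
    substr(genome[[chrom]], start + 1, start + motif_len) <<- motif
    invisible(start)
  }

  rows <- list()
  k_single <- 0L; k_double <- 0L
  for (i in seq_len(n_sv)) {
    cls <- classes[i]
    posA <- posA1[i]
    chromA <- "bg1"; chromB <- "bg2"; posB <- posBg2[i]
    ins <- ""
    if (cls == "none") {
      chromB <- "bg1"; posB <- posA2[i]
      svtype <- "deletion"; mech <- "other"
    } else if (cls == "single") {
      k_single <- k_single + 1L
      plant(chromA, posA, i)
      variant <- k_single %% 4L
      if (variant == 0L) {
        chromB <- "bg1"; posB <- posA2[i]
        svtype <- "deletion"; mech <- "cut_and_run_candidate"
      } else if (variant == 1L) {
        svtype <- "translocation"; mech <- "cut_and_run_candidate"
      } else if (variant == 2L) {
        # insertion: distinct clean anchor for the B side of the site
        chromB <- chromA; posB <- posA2[i]
        st <- 500 + (k_single * 137) %% (nchar(locus$sequence) - 900)
        ins <- substr0(locus$sequence, st, st + 200)
        svtype <- "complex_insertion"; mech <- "reintegration"
      } else {
        chromB <- chromA; posB <- posA2[i]
        ins <- random_dna(80)
        svtype <- "insertion"; mech <- "rag_insertion"
      }
    } else {
      k_double <- k_double + 1L
      if (k_double %% 2L == 0L) {
        chromB <- "bg1"; posB <- posA2[i]
        svtype <- "deletion"
      } else {
        svtype <- "translocation"
      }
      plant(chromA, posA, i)
      plant(chromB, posB, i + 7L)
      mech <- "two_cRSS_offtarget"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sv_id = sprintf("sv%03d", i), chromA = chromA, posA = posA,
      chromB = chromB, posB = posB, svtype_truth = svtype,
      insert_seq = ins, category_truth = cls, mechanism_truth = mech)
  }
  svs <- do.call(rbind, rows)
  rownames(svs) <- NULL
  list(svs = svs, genome = genome, loci_regions = loci_regions)
}
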