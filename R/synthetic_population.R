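#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. Defaults encode
#' the stated world the analyses assume: WGS-style fragments averaging
#' 500 bp with 35-50 bp sequenced ends, 2 x 250 bp overlapping LAM
#' amplicons, acentric circles segregating binomially at mitosis, and at
#' most one duplication per circle per cell cycle.
#'
#' @param n_founders founder cells (one clone each).
#' @param divisions cell divisions simulated per lineage.
#' @param esc_replication_prob probability `r` that a circle duplicates in a
#'   given cell cycle before segregation (0 = pure dilution, 1 = faithful
#'   once-per-cycle replication).
#' @param segregation `"binomial"` (each post-duplication copy picks a
#'   daughter independently, the acentric default) or `"even"` (copies are
#'   split as evenly as possible, remainder to daughter 1; analytic tests).
#' @param secondary_prob probability that a founder carries a secondary
#'   rearrangement on its other allele.
#' @param insert_len_max junctional-diversity insert length at coding joins
#'   is uniform on `0:insert_len_max`.
#' @param wgs_fragment_mean,wgs_fragment_sd fragment length distribution.
#' @param wgs_read_len sequenced bp at each fragment end (35-50).
#' @param lam_read_len LAM amplicon read length (2 x this per pair).
#' @param lam_amplicon_len LAM amplicon length (< 2*lam_read_len so the
#'   mates overlap).
#' @param lam_reads_per_copy expected sequencing reads per junction copy.
#' @param lam_noise_sd sd of the per-junction lognormal amplification
#'   efficiency factor.
#' @param seq_error_rate per-base substitution error rate.
#' @param seed integer seed (mandatory; every generator derives its stream
#'   from it).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 20, divisions = 6,
                       esc_replication_prob = 0.5,
                       segregation = c("binomial", "even"),
                       secondary_prob = 0.25, insert_len_max = 8,
                       wgs_fragment_mean = 500, wgs_fragment_sd = 60,
                       wgs_read_len = 45, lam_read_len = 250,
                       lam_amplicon_len = 320, lam_reads_per_copy = 30,
                       lam_noise_sd = 0.2, seq_error_rate = 0.001,
                       seed = NULL) {
  segregation <- match.arg(segregation)
  if (is.null(seed)) stopf("sim_config: seed is mandatory")
  r <- esc_replication_prob
  if (r < 0 || r > 1) stopf("esc_replication_prob must be in [0, 1]")
  if (wgs_read_len < 35 || wgs_read_len > 50)
    stopf("wgs_read_len must be in [35, 50]")
  if (lam_read_len <= 0 || wgs_read_len <= 0) stopf("read lengths positive")
  structure(list(n_founders = n_founders, divisions = divisions,
                 esc_replication_prob = r, segregation = segregation,
                 secondary_prob = secondary_prob,
                 insert_len_max = insert_len_max,
                 wgs_fragment_mean = wgs_fragment_mean,
                 wgs_fragment_sd = wgs_fragment_sd,
                 wgs_read_len = wgs_read_len, lam_read_len = lam_read_len,
                 lam_amplicon_len = lam_amplicon_len,
                 lam_reads_per_copy = lam_reads_per_copy,
                 lam_noise_sd = lam_noise_sd,
                 seq_error_rate = seq_error_rate, seed = seed),
            class = "sim_config")
}

# duplicate-then-segregate one generation of one event's copy vector.
# copies[k] = circle copies in cell k; returns vector of length 2*ncells
# (daughters of cell k at positions k and ncells+k).
segregate_once <- function(copies, r, segregation) {
  n <- length(copies)
  dup <- copies + rbinom(n, copies, r)
  if (segregation == "binomial") {
    d1 <- rbinom(n, dup, 0.5)
  } else {
    d1 <- dup %/% 2L + dup %% 2L  # remainder to daughter 1, deterministic
  }
  c(d1, dup - d1)
}

#' Simulate a clonal population carrying ESCs
#'
#' Each founder cell acquires a primary deletional rearrangement (drawn
#' uniformly from the locus' deletional pairs) on one allele, creating one
#' excised signal circle, and with probability `secondary_prob` a secondary
#' rearrangement on the other allele (biased towards the KDE join when the
#' locus has one, mimicking receptor editing). Coding joins carry a random
#' junctional insert so clonotypes are distinguishable. At every division
#' each circle copy duplicates with probability `r` and the resulting copies
#' segregate to the two daughters under the configured mode; chromosomal
#' recombination junctions are faithfully inherited by every descendant.
#'
#' @param cfg a [sim_config()].
#' @param locus an `IgLocus`.
#' @param db optional [enumerate_junctions()] database (built at flank 60 if
#'   missing).
#' @param junction_ids optional character vector restricting (and cycling
#'   through, founder by founder) the signal junctions assigned to founders;
#'   default samples uniformly.
#' @return object of class `population_truth`: list with
#'   \describe{
#'     \item{cells}{data.frame `cell_id`, `clone_id`.}
#'     \item{events}{data.frame `event_id`, `clone_id`, `sj_id`, `rec_id`,
#'       `partnerA`, `partnerB`, `allele`, `insert_seq`, `t` (divisions since
#'       the event).}
#'     \item{copies}{long data.frame `cell_id`, `event_id`, `copies` (> 0)
#'       of per-cell circle copies.}
#'     \item{totals}{per-event data.frame with `rec_copies` (`N2`, = carrier
#'       cells, one junction copy per cell), `sj_copies`, `t`.}
#'   }
#' @export
simulate_population <- function(cfg, locus, db = NULL, junction_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(locus, "IgLocus"))
  set.seed(derive_seed(cfg$seed, "population"))
  if (is.null(db)) db <- enumerate_junctions(locus)
  sj <- db[db$kind == "signal", ]
  if (nrow(sj) == 0) stopf("locus has no deletional pairs")
  if (is.null(junction_ids)) junction_ids <- sj$junction_id
  if (!all(junction_ids %in% sj$junction_id))
    stopf("unknown signal junction id")
  kde_ids <- sj$junction_id[sj$partnerA == "KDE"]

  events <- list()
  clone_events <- vector("list", cfg$n_founders)
  for (f in seq_len(cfg$n_founders)) {
    primary <- junction_ids[(f - 1L) %% length(junction_ids) + 1L]
    ev <- data.frame(clone_id = f, sj_id = primary, allele = 1L)
    if (runif(1) < cfg$secondary_prob) {
      pool <- if (length(kde_ids)) kde_ids else junction_ids
      ev <- rbind(ev, data.frame(clone_id = f,
                                 sj_id = sample(pool, 1L), allele = 2L))
    }
    clone_events[[f]] <- ev
  }
  events <- do.call(rbind, clone_events)
  events$event_id <- seq_len(nrow(events))
  m <- match(events$sj_id, sj$junction_id)
  events$rec_id <- sub("^SJ_", "REC_", events$sj_id)
  events$partnerA <- sj$partnerA[m]
  events$partnerB <- sj$partnerB[m]
  events$t <- cfg$divisions
  ins_len <- sample(0:cfg$insert_len_max, nrow(events), replace = TRUE)
  events$insert_seq <- vapply(ins_len, function(l)
    if (l == 0) "" else random_dna(l), character(1))

  cells <- list()
  copies_long <- list()
  for (f in seq_len(cfg$n_founders)) {
    ev <- events[events$clone_id == f, ]
    ncell <- 1L
    cop <- matrix(1L, nrow = 1L, ncol = nrow(ev))  # one circle per event
    for (d in seq_len(cfg$divisions)) {
      cop <- apply(cop, 2, segregate_once, r = cfg$esc_replication_prob,
                   segregation = cfg$segregation)
      cop <- matrix(cop, ncol = nrow(ev))
      ncell <- 2L * ncell
    }
    ids <- sprintf("c%d_%d", f, seq_len(ncell))
    cells[[f]] <- data.frame(cell_id = ids, clone_id = f)
    nz <- which(cop > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      copies_long[[f]] <- data.frame(
        cell_id = ids[nz[, 1]],
        event_id = ev$event_id[nz[, 2]],
        copies = cop[nz])
    }
  }
  cells <- do.call(rbind, cells)
  copies_long <- if (length(copies_long)) do.call(rbind, copies_long)
    else data.frame(cell_id = character(0), event_id = integer(0),
                    copies = integer(0))
  ncells_clone <- table(factor(cells$clone_id,
                               levels = seq_len(cfg$n_founders)))
  sj_tot <- tapply(copies_long$copies,
                   factor(copies_long$event_id, levels = events$event_id),
                   sum)
  totals <- data.frame(event_id = events$event_id,
                       sj_id = events$sj_id, rec_id = events$rec_id,
                       rec_copies = as.integer(ncells_clone[events$clone_id]),
                       sj_copies = as.integer(ifelse(is.na(sj_tot), 0, sj_tot)),
                       t = events$t)
  structure(list(cells = cells, events = events, copies = copies_long,
                 totals = totals, config = cfg, db = db),
            class = "population_truth")
}

#' Per-cell count of distinct circle species
#'
#' Counts, per cell, how many distinct events (optionally restricted, e.g.
#' to KDE-derived circles) the cell holds at least one circle copy of.
#'
#' @param truth a [simulate_population()] result.
#' @param event_ids optional restriction to a subset of event ids.
#' @return named integer vector over all cells (zeros included).
#' @export
distinct_circles_per_cell <- function(truth, event_ids = NULL) {
  cp <- truth$copies
  if (!is.null(event_ids)) cp <- cp[cp$event_id %in% event_ids, ]
  out <- setNames(integer(nrow(truth$cells)), truth$cells$cell_id)
  if (nrow(cp)) {
    tab <- table(cp$cell_id[cp$copies > 0])
    out[names(tab)] <- as.integer(tab)
  }
  out
}
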