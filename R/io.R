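#' Read / write FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as named character
#' vectors, the package's working representation.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a FASTQ file with constant Phred-30 qualities
#'
#' The pipeline uses base quality only for overlap-merge tie-breaking, so
#' simulated reads carry a constant quality string.
#'
#' @param seqs named character vector of reads.
#' @param path output path.
#' @export
write_fastq <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep("?", nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path file path.
#' @return named character vector of reads (qualities dropped).
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4 != 0) stopf("truncated FASTQ record in %s", path)
  ids <- sub("^@", "", ln[seq(1, length(ln), by = 4)])
  ids <- sub("\\s.*", "", ids)
  setNames(ln[seq(2, length(ln), by = 4)], ids)
}

#' Read a FASTQ pair, enforcing matching read ids
#'
#' @param path1,path2 mate files.
#' @return list `r1`, `r2` (named character vectors, same order).
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (!identical(names(r1), names(r2))) {
    bad <- setdiff(names(r1), names(r2))
    if (!length(bad)) bad <- setdiff(names(r2), names(r1))
    if (!length(bad)) bad <- names(r1)[names(r1) != names(r2)][1]
    stopf("read id mismatch between mates: %s", bad[1])
  }
  list(r1 = r1, r2 = r2)
}

#' Read / write BED intervals
#'
#' Plain BED (3+ columns, 0-based half-open); degenerate intervals with
#' `start >= end` are rejected.
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end` (+ `name`, `score`,
#'   `strand` when present).
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, comment.char = "#")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- nm[seq_len(min(ncol(x), 6))]
  if (any(x$start >= x$end)) {
    i <- which(x$start >= x$end)[1]
    stopf("BED interval with start >= end at line %d", i)
  }
  x
}

#' @rdname read_bed
#' @param bed data.frame with at least `chrom`, `start`, `end`.
#' @export
write_bed <- function(bed, path) {
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Serialize a locus to FASTA + BED
#'
#' The BED carries one line per segment plus one per RSS (name encodes the
#' RSS geometry) so that [read_locus()] can reconstruct the locus exactly.
#'
#' @param locus an `IgLocus`.
#' @param fasta_path,bed_path output paths.
#' @export
write_locus <- function(locus, fasta_path, bed_path) {
  write_fasta(setNames(locus$sequence, locus$name), fasta_path)
  s <- locus$segments
  seg_lines <- data.frame(chrom = locus$name, start = s$start, end = s$end,
                          name = paste("seg", s$name, s$kind, sep = "|"),
                          score = 0, strand = s$strand)
  has_rss <- !is.na(s$hept_start)
  rss_lines <- data.frame(
    chrom = locus$name,
    start = ifelse(s$rss_strand[has_rss] == "+", s$hept_start[has_rss],
                   s$hept_start[has_rss] - s$spacer_len[has_rss] - 9L),
    end = ifelse(s$rss_strand[has_rss] == "+",
                 s$hept_start[has_rss] + 16L + s$spacer_len[has_rss],
                 s$hept_start[has_rss] + 7L),
    name = paste("rss", s$name[has_rss], s$spacer_class[has_rss],
                 s$spacer_len[has_rss], s$hept_start[has_rss],
                 s$boundary[has_rss], sep = "|"),
    score = 0, strand = s$rss_strand[has_rss])
  write_bed(rbind(seg_lines, rss_lines), bed_path)
  invisible(locus)
}

#' Reconstruct a locus from FASTA + BED written by [write_locus()]
#'
#' @param fasta_path,bed_path input paths.
#' @param config the original [locus_config()] (motifs and allele count are
#'   not BED-encodable); defaults to a fresh default config.
#' @return an `IgLocus`.
#' @export
read_locus <- function(fasta_path, bed_path, config = locus_config()) {
  fa <- read_fasta(fasta_path)
  bed <- read_bed(bed_path)
  segb <- bed[startsWith(bed$name, "seg|"), ]
  rssb <- bed[startsWith(bed$name, "rss|"), ]
  parts <- strsplit(segb$name, "|", fixed = TRUE)
  rparts <- strsplit(rssb$name, "|", fixed = TRUE)
  rnames <- vapply(rparts, `[[`, character(1), 2)
  segs <- data.frame(
    name = vapply(parts, `[[`, character(1), 2),
    kind = vapply(parts, `[[`, character(1), 3),
    start = segb$start, end = segb$end, strand = segb$strand)
  m <- match(segs$name, rnames)
  segs$hept_start <- as.integer(vapply(rparts, `[[`, character(1), 5))[m]
  segs$spacer_class <- as.integer(vapply(rparts, `[[`, character(1), 3))[m]
  segs$spacer_len <- as.integer(vapply(rparts, `[[`, character(1), 4))[m]
  segs$rss_strand <- rssb$strand[m]
  segs$boundary <- as.integer(vapply(rparts, `[[`, character(1), 6))[m]
  locus <- structure(list(name = names(fa)[1], sequence = fa[[1]],
                          segments = segs, alleles = config$alleles,
                          config = config),
                     class = "IgLocus")
  validate_locus(locus)
  locus
}

#' Write alignment records as SAM
#'
#' Minimal SAM emission (header with \code{@SQ}, flags for pairing, strand,
#' mate number and supplementary status) for the package's alignment
#' tables, so external tools and [read_sam()] can consume them.
#'
#' @param alignments alignment data.frame (see [simulate_wgs_reads()]).
#' @param ref_lengths named integer vector of reference lengths.
#' @param path output path.
#' @export
write_sam <- function(alignments, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (rn in names(ref_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", rn, ref_lengths[[rn]]), con)
  }
  a <- alignments
  flag <- 1L +
    ifelse(a$strand == "-", 16L, 0L) +
    ifelse(a$mate == 1L, 64L, 128L) +
    ifelse(a$supplementary, 2048L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                   a$qname, flag, a$rname, a$pos + 1L, a$cigar,
                   ifelse(a$strand == "-", revcomp(a$seq), a$seq))
  writeLines(lines, con)
  invisible(path)
}

# cigar helpers: reference span consumed and leading clip
cigar_ref_len <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  sum(as.integer(sub("[A-Z=]", "", toks))[
    grepl("[MDN=X]", substring(toks, nchar(toks)))])
}

#' Read a SAM file into the package's alignment table
#'
#' Parses the text SAM format (header required); only the columns the
#' detector consumes are retained.
#'
#' @param path SAM path.
#' @return alignment data.frame (`qname`, `rname`, `pos` 0-based, `end`,
#'   `strand`, `cigar`, `mate`, `supplementary`, `seq`).
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  if (!length(ln) || !startsWith(ln[1], "@"))
    stopf("SAM without header: %s", path)
  body <- ln[!startsWith(ln, "@")]
  f <- strsplit(body, "\t")
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  cig <- vapply(f, `[[`, character(1), 6)
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  seq <- vapply(f, `[[`, character(1), 10)
  data.frame(
    qname = vapply(f, `[[`, character(1), 1),
    rname = vapply(f, `[[`, character(1), 3),
    pos = pos,
    end = pos + vapply(cig, cigar_ref_len, numeric(1)),
    strand = strand,
    cigar = cig,
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    supplementary = bitwAnd(flag, 2048L) > 0L,
    seq = ifelse(strand == "-", revcomp(seq), seq))
}

#' Write / read the junction database as TSV
#'
#' @param db a `junction_db`.
#' @param path file path.
#' @export
write_junction_db <- function(db, path) {
  write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junction_db
#' @export
read_junction_db <- function(path) {
  db <- read.delim(path, stringsAsFactors = FALSE)
  db$ref_seq <- as.character(db$ref_seq)
  class(db) <- c("junction_db", "data.frame")
  db
}
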