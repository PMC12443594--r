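#' @useDynLib esctools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rnorm runif rlnorm rpois setNames median
#'   complete.cases
#' @importFrom utils read.delim write.table head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors, which is how sequences travel through this package.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' @param n sequence length in bp.
#' @param gc GC content, default 0.4 (AT-rich intergenic background).
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_ALPHABET, n, replace = TRUE, prob = p), collapse = "")
}

# scalar reverse complement without Biostrings S4 overhead (hot paths)
revcomp1 <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

# substring on 0-based half-open coordinates (the package-wide convention)
substr0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# apply i.i.d. substitution errors at the given per-base rate
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit) {
      ch[i] <- sample(setdiff(DNA_ALPHABET, ch[i]), 1L)
    }
  }
  paste(ch, collapse = "")
}

# derive a reproducible stage seed (< 2^31) from a global seed and a label
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 100000L)) %% 2147483587L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
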