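#' Count k-mers over a set of reads
#'
#' Exhaustive in-memory k-mer counting. In canonical mode (the default,
#' matching common k-mer counter behaviour) each motif is stored as the
#' lexicographic minimum of itself and its reverse complement, merging
#' strands; stranded mode stores motifs as read. Windows containing
#' non-ACGT characters are skipped entirely.
#'
#' @param reads a \code{read_set}, named character vector, or
#'   \code{DNAStringSet}.
#' @param k motif length, >= 2 (supported up to 64 and beyond).
#' @param canonical merge a motif with its reverse complement?
#' @param genome_equivalents depth normalizer; taken from the
#'   \code{read_set} when available, else 1.
#' @return a \code{kmer_spectrum}: list with \code{k}, \code{counts}
#'   (named numeric, motif -> occurrences), \code{total_kmers},
#'   \code{genome_equivalents}.
#' @export
count_kmers <- function(reads, k, canonical = TRUE, genome_equivalents = NULL) {
  ge <- genome_equivalents
  if (inherits(reads, "read_set")) {
    ge <- ge %||% reads$genome_equivalents
    reads <- reads$reads
  }
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  if (!length(reads)) stop("reads must be non-empty")
  if (k < 2) stop("k must be >= 2")
  if (all(nchar(reads) < k)) stop("no countable k-mers: k exceeds every read length")
  res <- count_kmers_cpp(toupper(reads), as.integer(k), isTRUE(canonical))
  counts <- res$count
  names(counts) <- res$motif
  structure(list(k = as.integer(k), counts = counts,
                 total_kmers = res$total_kmers,
                 canonical = isTRUE(canonical),
                 genome_equivalents = ge %||% 1),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k = %d, %d distinct motifs, %.4g occurrences (%s)\n",
              x$k, length(x$counts), x$total_kmers,
              if (x$canonical) "canonical" else "stranded"))
  invisible(x)
}

#' Cumulative genome-repetitivity curve
#'
#' For each frequency threshold f (occurrences per genome equivalent),
#' the occurrence-weighted cumulative fraction of the read bases whose
#' motif occurs at or above f:
#' \deqn{C(f) = \sum_{m : n_m / GE \ge f} n_m / \sum_m n_m.}
#' C is non-increasing in f; the fraction is occurrence-weighted (a
#' genome fraction), not a count of distinct motifs.
#'
#' @param spectrum a \code{kmer_spectrum}.
#' @param thresholds numeric vector of per-genome-equivalent frequencies.
#' @return a \code{repetitivity_curve}: data.frame with columns \code{f}
#'   and \code{C}; attributes \code{k}, \code{genome_equivalents}.
#' @export
repetitivity_curve <- function(spectrum, thresholds) {
  if (!length(spectrum$counts)) stop("empty k-mer spectrum")
  if (!length(thresholds)) stop("thresholds must be non-empty")
  ge <- spectrum$genome_equivalents
  if (is.null(ge) || ge <= 0) stop("genome_equivalents must be positive")
  per_ge <- spectrum$counts / ge
  C <- vapply(thresholds, function(f)
    sum(spectrum$counts[per_ge >= f]) / spectrum$total_kmers, numeric(1))
  structure(data.frame(f = thresholds, C = C),
            class = c("repetitivity_curve", "data.frame"),
            k = spectrum$k, genome_equivalents = ge)
}

#' Genome fraction in motifs at or above one frequency threshold
#'
#' Convenience for the repetitivity curve at a single threshold.
#' @param spectrum a \code{kmer_spectrum}.
#' @param min_occ occurrences per genome equivalent.
#' @return scalar fraction in [0, 1].
#' @export
fraction_at <- function(spectrum, min_occ) {
  repetitivity_curve(spectrum, min_occ)$C
}

#' GC content of sequences
#'
#' (G+C) / (A+C+G+T), pooled over all input sequences; ambiguous bases
#' are excluded from the denominator.
#'
#' @param sequences character vector, \code{DNAStringSet} or
#'   \code{read_set}.
#' @return scalar fraction in [0, 1].
#' @export
gc_content <- function(sequences) {
  if (inherits(sequences, "read_set")) sequences <- sequences$reads
  if (!methods::is(sequences, "XStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  if (!length(sequences)) stop("input must be non-empty")
  af <- colSums(Biostrings::alphabetFrequency(sequences))
  denom <- sum(af[c("A", "C", "G", "T")])
  if (denom == 0) stop("all input bases are ambiguous")
  sum(af[c("G", "C")]) / denom
}
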