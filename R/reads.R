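#' Simulate paired-end reads from a genome
#'
#' Shotgun paired-end simulation emulating a 2 x 250 bp library from
#' 500 bp inserts: per sequence, \code{round(coverage * length /
#' (2 * read_length))} fragment positions are drawn uniformly; the
#' forward mate is the fragment's first \code{read_length} bases and the
#' reverse mate the reverse complement of its last \code{read_length}
#' bases. Errors are substitutions only. Read ids encode origin as
#' \code{<subgenome>_<pair#>_<start>/<mate>} (1-based fragment start).
#'
#' @param genome result of \code{\link{assemble_genome}}, or a named
#'   character vector of sequences.
#' @param spec a \code{\link{read_sim_spec}}.
#' @param seed integer seed; the run is reproducible given the seed.
#' @param stated_1C assumed 1C genome size (bp) used to express depth in
#'   genome equivalents; defaults to the realized total genome length.
#' @return a \code{read_set}: list with \code{reads} (named character
#'   vector over both mates), \code{read_length}, \code{total_bases},
#'   \code{stated_1C}, \code{genome_equivalents}.
#' @export
simulate_reads <- function(genome, spec, seed = 1L, stated_1C = NULL) {
  seqs <- if (is.list(genome) && !is.null(genome$sequences))
    genome$sequences else genome
  if (is.null(names(seqs))) names(seqs) <- paste0("S", seq_along(seqs))
  if (spec$coverage <= 0) stop("coverage must be positive")
  if (any(nchar(seqs) < spec$insert_length))
    stop("insert length exceeds a genome sequence length")
  rl <- spec$read_length
  res <- with_seed(seed, {
    out <- list()
    for (nm in names(seqs)) {
      s <- seqs[[nm]]
      L <- nchar(s)
      npair <- round(spec$coverage * L / (2 * rl))
      if (npair == 0) next
      starts <- sample.int(L - spec$insert_length + 1L, npair, replace = TRUE)
      frag1 <- substring(s, starts, starts + rl - 1L)
      frag2 <- revcomp(substring(s, starts + spec$insert_length - rl,
                                 starts + spec$insert_length - 1L))
      if (spec$error_rate > 0) {
        frag1 <- vapply(frag1, mutate_seq, character(1),
                        rate = spec$error_rate, USE.NAMES = FALSE)
        frag2 <- vapply(frag2, mutate_seq, character(1),
                        rate = spec$error_rate, USE.NAMES = FALSE)
      }
      ids <- sprintf("%s_%06d_%d", nm, seq_len(npair), starts)
      reads <- c(frag1, frag2)
      names(reads) <- c(paste0(ids, "/1"), paste0(ids, "/2"))
      out[[nm]] <- reads
    }
    unlist(out, use.names = TRUE)
  })
  # unlist() prefixes list names; strip back to the id encoded per read
  names(res) <- sub("^[^.]*\\.", "", names(res))
  total_bases <- sum(nchar(res))
  stated_1C <- stated_1C %||% sum(nchar(seqs))
  structure(list(reads = res, read_length = rl,
                 total_bases = total_bases, stated_1C = stated_1C,
                 genome_equivalents = total_bases / stated_1C,
                 sim_spec = spec),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads x %d bp, %.3g bases (%.2f genome equivalents)\n",
              length(x$reads), x$read_length, x$total_bases,
              x$genome_equivalents))
  invisible(x)
}

## Mate id helpers: ids end in /1 or /2.
mate_stem <- function(ids) sub("/[12]$", "", ids)
mate_of <- function(ids) {
  ifelse(grepl("/1$", ids), paste0(mate_stem(ids), "/2"),
         paste0(mate_stem(ids), "/1"))
}
read_subgenome <- function(ids) sub("_.*$", "", ids)

#' Write a read set as paired FASTQ
#'
#' Files \code{<prefix>_1.fastq} / \code{<prefix>_2.fastq}, Phred+33 with
#' fixed quality "I".
#'
#' @param read_set a \code{read_set}.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_read_fastq <- function(read_set, prefix) {
  ids <- names(read_set$reads)
  for (mate in 1:2) {
    sel <- grepl(paste0("/", mate, "$"), ids)
    ss <- Biostrings::DNAStringSet(read_set$reads[sel])
    qs <- Biostrings::BStringSet(strrep("I", nchar(read_set$reads[sel])))
    qss <- Biostrings::QualityScaledDNAStringSet(
      ss, Biostrings::PhredQuality(qs))
    Biostrings::writeQualityScaledXStringSet(
      qss, paste0(prefix, "_", mate, ".fastq"))
  }
  invisible(paste0(prefix, "_", 1:2, ".fastq"))
}

#' Read sequences from FASTA/FASTQ into a plain named character vector
#'
#' @param path file path; format inferred from extension.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
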