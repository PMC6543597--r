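#' @useDynLib repeatscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse complement of character sequences
#'
#' Thin wrapper over the compiled kernel; ambiguous characters map to N.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements, names preserved.
#' @export
revcomp <- function(x) revcomp_cpp(toupper(as.character(x)))

## Evaluate expr under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Deterministic per-stage seed derived from one root seed (kept < 2^31).
derive_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1)
  off <- sum(utf8ToInt(as.character(stage)))
  as.integer((as.numeric(root) * 7919 + off * 104729) %% 2147483647L)
}

## Random DNA of a given GC fraction (no seed handling here).
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

## Substitution-only mutation at a fixed per-base rate; each hit base is
## replaced by one of the three alternatives uniformly.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hits <- which(stats::runif(n) < rate)
  if (!length(hits)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in hits) {
    alt <- setdiff(BASES, ch[i])
    ch[i] <- alt[sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

## Shannon entropy (bits) of the dinucleotide composition of a sequence.
dinucleotide_entropy <- function(seq) {
  n <- nchar(seq)
  if (n < 2) return(0)
  di <- substring(seq, 1:(n - 1), 2:n)
  di <- di[!grepl("[^ACGT]", di)]
  if (!length(di)) return(0)
  p <- table(di) / length(di)
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
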