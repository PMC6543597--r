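#' Find qualifying read-overlap edges
#'
#' Computes the edges of the read-overlap graph under the clustering
#' edge criterion: two reads are joined when some overlap alignment, on
#' either strand, spans at least \code{min_overlap_frac} of the shorter
#' read at identity at least \code{min_identity} (matches / alignment
#' columns within the overlapping segment). Candidate overlaps are found
#' by an exact-seed prefilter (shared \code{seed_len}-mers) followed by
#' gap-free extension along the best-supported diagonals; with a
#' substitution-only error model the optimal overlap alignment is
#' gap-free, and small instances are checked against a full
#' dynamic-programming oracle in the test suite.
#'
#' @param reads named character vector of read sequences (unique names),
#'   or a \code{read_set}.
#' @param min_overlap_frac minimum overlap as a fraction of the shorter
#'   read (default 0.5).
#' @param min_identity minimum identity within the overlap (default 0.9).
#' @param seed_len exact-seed length for the prefilter.
#' @param index_step seed sampling stride on indexed reads.
#' @param max_diags diagonals evaluated per read pair and strand.
#' @param max_seed_occ cap on postings per seed value (abundant
#'   satellite seeds are deterministically downsampled).
#' @return data.frame of class \code{overlap_edges}: \code{read_a},
#'   \code{read_b}, \code{strand} ("+" same / "-" opposite),
#'   \code{overlap}, \code{matches}, \code{identity}, \code{offset}
#'   (start of the strand-oriented read_b in read_a coordinates).
#' @export
find_overlaps <- function(reads, min_overlap_frac = 0.5, min_identity = 0.9,
                          seed_len = 14L, index_step = 5L, max_diags = 8L,
                          max_seed_occ = 5000L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  ids <- names(reads)
  if (is.null(ids) || anyDuplicated(ids))
    stop("reads must be deduplicated by id (unique names required)")
  df <- find_overlaps_cpp(toupper(unname(reads)), min_overlap_frac,
                          min_identity, as.integer(seed_len),
                          as.integer(index_step), as.integer(max_diags),
                          as.integer(max_seed_occ))
  out <- data.frame(read_a = ids[df$a], read_b = ids[df$b],
                    strand = df$strand, overlap = df$overlap,
                    matches = df$matches, identity = df$identity,
                    offset = df$offset, stringsAsFactors = FALSE)
  out <- out[order(out$read_a, out$read_b, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("overlap_edges", "data.frame"),
            read_ids = ids)
}
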