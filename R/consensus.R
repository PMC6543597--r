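#' Build a cluster consensus by greedy overlap layout
#'
#' Deterministic greedy overlap-layout-consensus over the member reads
#' of one cluster: the seed is the read of highest overlap degree (ties
#' by lexicographically smallest id); the remaining reads are placed
#' along a maximum-weight spanning tree of the overlap graph (weight =
#' identity x overlap), propagating each edge's strand and diagonal
#' offset; the consensus is the column-wise majority vote over placed
#' reads, ties breaking lexicographically (A<C<G<T).
#'
#' For tandem-repeat clusters the relative placements are only defined
#' up to multiples of the monomer, which leaves the consensus periodic
#' with the correct period: exactly what downstream periodicity analysis
#' needs.
#'
#' @param reads named character vector: the cluster's member reads.
#' After voting, the consensus is trimmed to its longest well-supported
#' run of columns (support at least \code{trim_frac} of the maximum):
#' reads straddling a repeat/background boundary hang their flanking
#' sequence off the layout at low support, and those ragged margins
#' would otherwise dilute periodicity and domain signals.
#'
#' @param edges optional precomputed \code{overlap_edges} restricted to
#'   these reads; computed when NULL.
#' @param trim_frac support threshold for trimming, as a fraction of the
#'   maximum column support (default 0.1; 0 disables trimming).
#' @param fold_palindromes collapse a palindromic consensus (an element
#'   copy stitched head-to-head against a reverse-complement copy, an
#'   artifact of strand-ambiguous layouts over dispersed repeats) down
#'   to its longer arm (default TRUE).
#' @param ... passed to \code{\link{find_overlaps}} when edges are
#'   computed here.
#' @return a \code{consensus_seq}: list with \code{sequence},
#'   \code{support} (reads covering each column), \code{n_reads},
#'   \code{placed} (placement table).
#' @export
build_consensus <- function(reads, edges = NULL, trim_frac = 0.1,
                            fold_palindromes = TRUE, ...) {
  if (!length(reads)) stop("at least one read required")
  reads <- reads[order(names(reads))]
  if (length(reads) == 1L)
    return(structure(list(sequence = unname(reads[1]),
                          support = rep(1L, nchar(reads[1])),
                          n_reads = 1L,
                          placed = data.frame(id = names(reads), pos = 0L,
                                              orient = 1L)),
                     class = "consensus_seq"))
  if (is.null(edges)) edges <- find_overlaps(reads, ...)
  ids <- names(reads)
  if (nrow(edges)) {
    # one edge per pair: keep the most informative (identity x extension)
    sc <- edges$identity * (1 + abs(edges$offset))
    ord <- order(edges$read_a, edges$read_b, -sc)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(edges[, c("read_a", "read_b")]), , drop = FALSE]
  }
  if (!nrow(edges)) {
    # no qualifying overlaps: consensus of the longest read alone
    longest <- ids[which.max(nchar(reads))]
    return(structure(list(sequence = unname(reads[longest]),
                          support = rep(1L, nchar(reads[longest])),
                          n_reads = length(reads),
                          placed = data.frame(id = longest, pos = 0L,
                                              orient = 1L)),
                     class = "consensus_seq"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$read_a, to = edges$read_b),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  igraph::E(g)$eidx <- seq_len(nrow(edges))
  # maximum spanning tree favouring high-identity *extending* overlaps:
  # offset-0 stacks carry no layout information, so weight each edge by
  # identity times how far it advances the layout. This keeps tandem
  # arrays from collapsing onto a single monomer-length window.
  igraph::E(g)$weight <- -(edges$identity * (1 + abs(edges$offset)))
  tr <- igraph::mst(g)
  deg <- igraph::degree(g)
  seedv <- names(which(deg == max(deg)))
  seedv <- sort(seedv)[1]
  comp <- igraph::components(tr)
  seed_comp <- comp$membership[seedv]
  lens <- nchar(reads)
  pos <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  ori <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  pos[seedv] <- 0L; ori[seedv] <- 1L
  bf <- igraph::bfs(tr, root = seedv, unreachable = FALSE, father = TRUE)
  ovec <- as.numeric(bf$order)
  order_v <- names(igraph::V(tr))[ovec[!is.na(ovec)]]
  fvec <- as.numeric(bf$father)
  fathers <- stats::setNames(ifelse(is.na(fvec), NA_character_,
                                    names(igraph::V(tr))[fvec]),
                             names(igraph::V(tr)))
  for (v in order_v) {
    if (v == seedv) next
    f <- fathers[v]
    if (is.na(f)) next
    eid <- igraph::get_edge_ids(tr, c(f, v))
    e <- edges[igraph::E(tr)$eidx[eid], ]
    # orient the edge as (a = father, b = child)
    if (e$read_a == f) {
      s <- if (e$strand == "+") 1L else -1L
      d <- e$offset
    } else {
      s <- if (e$strand == "+") 1L else -1L
      d <- if (e$strand == "+") -e$offset
           else e$offset + lens[e$read_b] - lens[e$read_a]
    }
    if (ori[f] == 1L) {
      ori[v] <- s
      pos[v] <- pos[f] + d
    } else {
      ori[v] <- -s
      pos[v] <- pos[f] + lens[f] - d - lens[v]
    }
  }
  placed <- !is.na(pos)
  pids <- ids[placed]
  shift <- min(pos[pids])
  offs <- pos[pids] - shift
  oriented <- ifelse(ori[pids] == 1L, reads[pids], revcomp(reads[pids]))
  cv <- consensus_vote_cpp(unname(oriented), as.integer(offs))
  seqc <- cv$consensus
  supp <- cv$support
  if (trim_frac > 0 && length(supp)) {
    # relative to the peak, but never below half the typical support:
    # at low coverage the peak alone under-trims ragged flanks
    thr <- max(2, ceiling(trim_frac * max(supp)),
               ceiling(0.5 * stats::median(supp)))
    ok <- supp >= thr
    if (any(ok)) {
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      best <- runs[which.max(r$lengths[runs])]
      seqc <- substr(seqc, starts[best], ends[best])
      supp <- supp[starts[best]:ends[best]]
    }
  }
  if (fold_palindromes && nchar(seqc) >= 100) {
    fold <- fold_palindrome(seqc, supp)
    seqc <- fold$sequence
    supp <- fold$support
  }
  structure(list(sequence = seqc, support = supp,
                 n_reads = length(reads),
                 placed = data.frame(id = pids, pos = as.integer(offs),
                                     orient = as.integer(ori[pids]),
                                     stringsAsFactors = FALSE)),
            class = "consensus_seq")
}

## Detect a mirrored (reverse-complement self-matching) consensus and
## keep only its longer arm. The mirror is found with the same seeded
## gap-free overlap engine used for read overlaps, requiring the
## opposite-strand self-match to span at least half the consensus.
fold_palindrome <- function(seqc, supp) {
  L <- nchar(seqc)
  e <- tryCatch(
    find_overlaps(c(armA = seqc, armB = seqc),
                  min_overlap_frac = 0.5, min_identity = 0.8,
                  index_step = 3L, max_diags = 12L),
    error = function(cond) NULL)
  out <- list(sequence = seqc, support = supp)
  if (is.null(e) || !nrow(e)) return(out)
  em <- e[e$strand == "-", , drop = FALSE]
  if (!nrow(em)) return(out)
  em <- em[order(-em$overlap), , drop = FALSE]
  # s[x] pairs with s[L-1-x+d]; the fixed point is the mirror centre
  centre <- as.integer(round((L - 1 + em$offset[1]) / 2)) + 1L
  if (centre < 50 || centre > L - 50) {
    # mirror centre at the very end: the arms coincide; keep as is
    return(out)
  }
  if (centre >= L - centre) {
    list(sequence = substr(seqc, 1L, centre), support = supp[1:centre])
  } else {
    list(sequence = substr(seqc, centre + 1L, L),
         support = supp[(centre + 1L):L])
  }
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("consensus_seq: %d bp from %d reads (mean support %.1f)\n",
              nchar(x$sequence), x$n_reads, mean(x$support)))
  invisible(x)
}
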