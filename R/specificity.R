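#' Count reads mapping to a reference fragment
#'
#' "Map to Reference"-style counting: a read counts (at most once) when
#' its best local alignment to the fragment, on either strand, covers at
#' least \code{min_read_coverage} of the read at \code{min_identity} or
#' better. With the substitution-only error model the best alignment is
#' gap-free and found by seeded diagonal evaluation.
#'
#' @param reads named character vector or \code{read_set}.
#' @param fragment character scalar, length >= 30.
#' @param min_identity default 0.9.
#' @param min_read_coverage default 0.5 of the read length.
#' @param seed_len exact-seed length for candidate diagonals.
#' @return integer mapped-read count, with attribute \code{mapped}
#'   (logical per read).
#' @export
map_reads <- function(reads, fragment, min_identity = 0.9,
                      min_read_coverage = 0.5, seed_len = 14L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  if (is.null(fragment) || !nzchar(fragment)) stop("empty fragment")
  if (nchar(fragment) < 30) stop("fragment length must be >= 30")
  hit <- map_reads_cpp(toupper(unname(reads)), toupper(fragment),
                       min_identity, min_read_coverage, as.integer(seed_len))
  names(hit) <- names(reads)
  structure(sum(hit), mapped = hit)
}

#' Copies per 1C genome from mapped-read counts
#'
#' Base-normalized estimator (default):
#' \deqn{copies = mapped\_reads \times read\_length /
#'   (fragment\_length \times genome\_equivalents)}
#' i.e. bases mapped per genome equivalent divided by fragment length.
#' \code{mode = "read"} reports raw reads per genome equivalent (the
#' literal "number of reads per genome equivalent"), without length
#' normalization. The estimate is invariant to coverage in expectation.
#'
#' @param mapped_reads non-negative count.
#' @param read_length,fragment_length bp.
#' @param genome_equivalents sequencing depth in genome equivalents
#'   (total bases / stated 1C size).
#' @param mode \code{"base"} (default) or \code{"read"}.
#' @return scalar copy-number estimate.
#' @export
copies_per_1C <- function(mapped_reads, read_length, fragment_length,
                          genome_equivalents, mode = c("base", "read")) {
  mode <- match.arg(mode)
  if (genome_equivalents <= 0) stop("genome_equivalents must be positive")
  if (mapped_reads < 0) stop("mapped_reads must be >= 0")
  if (read_length <= 0 || fragment_length <= 0)
    stop("lengths must be positive")
  if (mode == "base")
    as.numeric(mapped_reads) * read_length / (fragment_length * genome_equivalents)
  else as.numeric(mapped_reads) / genome_equivalents
}

#' Classify a repeat fragment's genome specificity
#'
#' The qualifying set is the subgenomes whose copy number is at least
#' \code{alpha} times the maximum across subgenomes and at least
#' \code{floor} copies. The set maps onto the configured categories
#' (singletons, a stated multi-genome combination such as A+D, and
#' all-genomes); a qualifying set matching no configured category is
#' assigned the smallest configured superset with a warning flag, so
#' unexpected combinations remain observable. When every subgenome is
#' below \code{floor} the fragment is reported \code{"undetected"}.
#'
#' @param copies named numeric vector: copies per 1C per subgenome
#'   sample (>= 2 samples).
#' @param alpha relative-abundance threshold (default 0.2).
#' @param floor minimum copies per 1C to count as present (default 10).
#' @param categories list of character vectors of allowed qualifying
#'   sets; defaults to all singletons plus \code{c("A","D")} (when both
#'   labels exist) plus all genomes.
#' @return a \code{specificity_call}: list with \code{category},
#'   \code{qualifying}, \code{copies}, \code{warning_flag},
#'   \code{evidence}.
#' @export
classify_specificity <- function(copies, alpha = 0.2, floor = 10,
                                 categories = NULL) {
  if (length(copies) < 2 || is.null(names(copies)))
    stop("copies must be a named vector over >= 2 subgenome samples")
  labs <- names(copies)
  if (is.null(categories)) {
    categories <- as.list(labs)
    if (all(c("A", "D") %in% labs)) categories <- c(categories, list(c("A", "D")))
    categories <- c(categories, list(labs))
  }
  categories <- lapply(categories, function(s) sort(s))
  cat_label <- function(s) {
    if (setequal(s, labs)) "all-genomes"
    else paste0(paste(sort(s), collapse = "+"), "-specific")
  }
  mx <- max(copies)
  qual <- sort(labs[copies >= alpha * mx & copies >= floor])
  if (!length(qual)) {
    return(structure(list(category = "undetected", qualifying = character(),
                          copies = copies, warning_flag = FALSE,
                          evidence = "all samples below detection floor"),
                     class = "specificity_call"))
  }
  hit <- which(vapply(categories, function(s) setequal(s, qual), logical(1)))
  if (length(hit)) {
    return(structure(list(category = cat_label(categories[[hit[1]]]),
                          qualifying = qual, copies = copies,
                          warning_flag = FALSE, evidence = ""),
                     class = "specificity_call"))
  }
  sup <- categories[vapply(categories, function(s) all(qual %in% s), logical(1))]
  sup <- sup[order(vapply(sup, length, integer(1)))]
  structure(list(category = cat_label(sup[[1]]), qualifying = qual,
                 copies = copies, warning_flag = TRUE,
                 evidence = paste0("qualifying set {",
                                   paste(qual, collapse = ","),
                                   "} matches no configured category")),
            class = "specificity_call")
}

#' @export
print.specificity_call <- function(x, ...) {
  cat(sprintf("specificity_call: %s%s (copies: %s)\n", x$category,
              if (x$warning_flag) " [warning]" else "",
              paste(sprintf("%s=%.1f", names(x$copies), x$copies),
                    collapse = ", ")))
  invisible(x)
}

#' Select probe candidate fragments from cluster consensi
#'
#' One candidate per qualifying cluster: the cluster must have at most
#' \code{max_neighbours} first-order neighbours (discrete repeat
#' families make clean probes) and a consensus at least the minimum
#' length; the candidate is the central slice of the consensus within
#' the length range, rejected if its dinucleotide entropy falls below
#' \code{min_entropy} bits (low-complexity filter).
#'
#' @param cluster_table a \code{cluster_table}.
#' @param neighbours a \code{cluster_neighbour_graph}.
#' @param consensi named list (by cluster id) of \code{consensus_seq} or
#'   character.
#' @param length_range numeric c(min, max) fragment length (bp).
#' @param max_neighbours maximum first-order neighbours (default 1).
#' @param min_entropy dinucleotide entropy floor in bits (default 1.5).
#' @return data.frame of class \code{probe_candidates}: \code{cluster_id},
#'   \code{length}, \code{neighbour_count}, \code{complexity},
#'   \code{sequence}.
#' @export
select_probes <- function(cluster_table, neighbours, consensi,
                          length_range = c(80, 600), max_neighbours = 1L,
                          min_entropy = 1.5) {
  rows <- list()
  for (i in seq_len(nrow(cluster_table))) {
    cid <- cluster_table$cluster_id[i]
    key <- as.character(cid)
    cons <- consensi[[key]]
    if (is.null(cons)) next
    support <- NULL
    if (inherits(cons, "consensus_seq")) {
      support <- cons$support
      cons <- cons$sequence
    }
    nb <- neighbours$neighbour_count[sprintf("CL%d", cid)]
    if (is.na(nb) || nb > max_neighbours) next
    L <- nchar(cons)
    if (L < length_range[1]) next
    flen <- min(L, length_range[2])
    if (!is.null(support) && L > flen) {
      # place the fragment on the best-supported window of the consensus
      cum <- cumsum(c(0, support))
      starts <- seq(0L, L - flen, by = 10L)
      st <- starts[which.max(cum[starts + flen + 1L] - cum[starts + 1L])]
    } else {
      st <- (L - flen) %/% 2L
    }
    frag <- substr(cons, st + 1L, st + flen)
    ent <- dinucleotide_entropy(frag)
    if (ent < min_entropy) next
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cid, length = as.integer(flen),
      neighbour_count = as.integer(nb),
      complexity = ent, sequence = frag, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), length = integer(),
               neighbour_count = integer(), complexity = numeric(),
               sequence = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("probe_candidates", "data.frame"))
}
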