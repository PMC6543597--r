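#' Scan a consensus for domain exemplar hits
#'
#' Local alignment of every library exemplar against the consensus and
#' its reverse complement (Smith-Waterman via
#' \code{Biostrings::pairwiseAlignment}); hits meeting the identity and
#' exemplar-coverage thresholds are reported with 0-based half-open
#' coordinates on the forward consensus. Overlapping hits for the same
#' domain are merged keeping the best identity.
#'
#' @param consensus character scalar (or \code{consensus_seq}).
#' @param library an \code{exemplar_library}.
#' @param min_identity matches / alignment columns, default 0.7.
#' @param min_coverage aligned fraction of the exemplar, default 0.5.
#' @return data.frame of class \code{domain_hits}: \code{domain_id},
#'   \code{start}, \code{end}, \code{strand}, \code{identity},
#'   \code{coverage}.
#' @export
scan_domains <- function(consensus, library, min_identity = 0.7,
                         min_coverage = 0.5) {
  if (inherits(consensus, "consensus_seq")) consensus <- consensus$sequence
  if (is.null(library) || !nrow(library)) stop("empty exemplar library")
  L <- nchar(consensus)
  subj <- Biostrings::DNAString(consensus)
  subj_rc <- Biostrings::reverseComplement(subj)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  hits <- list()
  for (i in seq_len(nrow(library))) {
    ex <- library$sequence[i]
    exlen <- nchar(ex)
    if (L < 30) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") subj else subj_rc
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(ex), s, type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (cols == 0) next
      ident <- Biostrings::nmatch(aln) / cols
      pat_rng <- aln@pattern@range
      cov <- IRanges::width(pat_rng) / exlen
      if (ident < min_identity || cov < min_coverage) next
      st <- IRanges::start(aln@subject@range) - 1L
      en <- IRanges::end(aln@subject@range)
      if (strand == "-") { tmp <- st; st <- L - en; en <- L - tmp }
      hits[[length(hits) + 1L]] <- data.frame(
        domain_id = library$domain_id[i], start = st, end = en,
        strand = strand, identity = ident, coverage = cov,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(structure(data.frame(domain_id = character(), start = integer(),
                                end = integer(), strand = character(),
                                identity = numeric(), coverage = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("domain_hits", "data.frame")))
  df <- do.call(rbind, hits)
  # merge overlapping hits of the same domain, keeping the best identity
  keep <- rep(TRUE, nrow(df))
  for (d in unique(df$domain_id)) {
    idx <- which(df$domain_id == d)
    idx <- idx[order(-df$identity[idx])]
    taken <- logical(0)
    sel <- integer(0)
    for (j in idx) {
      ov <- any(vapply(sel, function(k)
        df$start[j] < df$end[k] && df$end[j] > df$start[k], logical(1)))
      if (ov) keep[j] <- FALSE else sel <- c(sel, j)
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start, df$domain_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("domain_hits", "data.frame"))
}

RETRO_DOMAINS <- c("RT", "RH", "INT")

#' Classify a consensus into a repeat superfamily by domain order
#'
#' Rule-based call: with RT, RH and INT all present, the 5'-to-3' order
#' on the strand carrying the majority of retro-domain hits decides
#' Gypsy (RT-RH-INT) versus Copia (INT-RT-RH); rDNA exemplar hits call
#' rDNA; TRANSPOSASE without retro domains calls DNA_transposon; RT
#' without INT is a low-confidence LINE call; strong tandem periodicity
#' without domain hits calls tandem/satellite; anything else is
#' unclassified. Duplicated domains with conflicting order give
#' unclassified with an evidence note (not an error). Classifying a
#' consensus and its reverse complement yields the same call.
#'
#' @param hits a \code{domain_hits} data.frame from one consensus.
#' @param periodicity optional \code{monomer_call} (or its
#'   classification string) providing tandem-periodicity evidence.
#' @return a \code{superfamily_call}: list with \code{category},
#'   \code{evidence}, \code{low_confidence}, \code{note}.
#' @export
classify_superfamily <- function(hits, periodicity = NULL) {
  per_class <- if (inherits(periodicity, "monomer_call"))
    periodicity$classification else periodicity %||% "none"
  periodic <- per_class %in% c("simple_tandem", "higher_order")
  call <- function(category, evidence = character(), low = FALSE, note = "")
    structure(list(category = category, evidence = evidence,
                   low_confidence = low, note = note),
              class = "superfamily_call")
  if (!is.null(hits) && nrow(hits)) {
    retro <- hits[hits$domain_id %in% RETRO_DOMAINS, , drop = FALSE]
    if (nrow(retro) && all(RETRO_DOMAINS %in% retro$domain_id)) {
      # evaluate the domain order carried by one strand; NULL when the
      # strand lacks the full trio, NA on conflicting duplicate order
      strand_order <- function(strand) {
        rs <- retro[retro$strand == strand, , drop = FALSE]
        if (!all(RETRO_DOMAINS %in% rs$domain_id)) return(NULL)
        rs <- rs[order(-rs$identity), , drop = FALSE]
        best <- rs[!duplicated(rs$domain_id), , drop = FALSE]
        sgn <- if (strand == "+") 1 else -1
        conflict <- FALSE
        for (d in RETRO_DOMAINS) {
          dd <- rs[rs$domain_id == d, , drop = FALSE]
          if (nrow(dd) > 1) {
            ords <- vapply(seq_len(nrow(dd)), function(j) {
              b2 <- best; b2[b2$domain_id == d, ] <- dd[j, ]
              paste(b2$domain_id[order(b2$start * sgn)], collapse = "-")
            }, character(1))
            if (length(unique(ords)) > 1) conflict <- TRUE
          }
        }
        if (conflict) return(NA_character_)
        paste(best$domain_id[order(best$start * sgn)], collapse = "-")
      }
      as_category <- function(ord) {
        if (is.null(ord)) return(NULL)
        if (is.na(ord)) return(NA_character_)
        switch(ord, "RT-RH-INT" = "Gypsy", "INT-RT-RH" = "Copia",
               "other")
      }
      n_plus <- sum(retro$strand == "+")
      n_minus <- sum(retro$strand == "-")
      if (n_plus != n_minus) {
        maj <- if (n_plus > n_minus) "+" else "-"
        ord <- strand_order(maj)
        if (is.null(ord))
          return(call("unclassified",
                      note = "retro domains split across strands"))
        ctg <- as_category(ord)
        if (is.na(ctg))
          return(call("unclassified",
                      note = "duplicated domains with conflicting order"))
        if (ctg == "other")
          return(call("unclassified", evidence = ord,
                      note = "retro domain order matches neither superfamily"))
        return(call(ctg, evidence = ord))
      }
      # strand tie: accept only if both strands independently agree
      # (e.g. a layout that stitched two element copies head-to-head)
      cp <- as_category(strand_order("+"))
      cm <- as_category(strand_order("-"))
      if (!is.null(cp) && !is.null(cm) && !is.na(cp) && !is.na(cm) &&
          cp == cm && cp != "other")
        return(call(cp, evidence = "both strands agree"))
      return(call("unclassified",
                  note = "retro domains split equally across strands"))
    }
    if (any(grepl("^rDNA", hits$domain_id)))
      return(call("rDNA",
                  evidence = hits$domain_id[grepl("^rDNA", hits$domain_id)]))
    if ("TRANSPOSASE" %in% hits$domain_id && !nrow(retro))
      return(call("DNA_transposon", evidence = "TRANSPOSASE"))
    if ("RT" %in% retro$domain_id && !("INT" %in% retro$domain_id))
      return(call("LINE", evidence = retro$domain_id, low = TRUE,
                  note = "RT without INT: low-confidence LINE"))
  }
  if (periodic)
    return(call("tandem/satellite", evidence = paste0("periodicity:", per_class)))
  call("unclassified")
}

#' Classify the shape of a cluster's overlap graph
#'
#' Computes graph metrics and applies ordered rules mirroring the visual
#' shape vocabulary used for cluster graphs (circular for tandem repeats
#' longer than a read, line for simple repeats, star for short
#' satellites, ray for retroelements): (1) a long chordless cycle (girth
#' >= 8 of the pendant-pruned 2-core) gives \emph{circle}; (2)
#' normalized diameter >= \code{diam_min} gives \emph{line}; (3) hub
#' dominance (max/mean degree) >= \code{hub_min} gives \emph{star}; (4)
#' pendant-path mass >= \code{pendant_min} off a dense core gives
#' \emph{ray}; otherwise \emph{amorphous}. Graphs under 10 nodes are
#' amorphous.
#'
#' @param subgraph an igraph object (one cluster's overlap subgraph).
#' @param hub_min,diam_min,pendant_min rule thresholds (calibrated on
#'   constructed graphs; exposed for configuration).
#' @return a \code{shape_call}: list with \code{shape} and \code{metrics}
#'   (hub_dominance, normalized_diameter, cycle_flag, density,
#'   pendant_mass).
#' @export
classify_shape <- function(subgraph, hub_min = 5, diam_min = 0.5,
                           pendant_min = 0.3) {
  n <- igraph::vcount(subgraph)
  deg <- igraph::degree(subgraph)
  metrics <- list(hub_dominance = if (n) max(deg) / max(mean(deg), 1e-9) else 0,
                  normalized_diameter = if (n)
                    igraph::diameter(subgraph, weights = NA) / n else 0,
                  cycle_flag = FALSE, density = igraph::edge_density(subgraph),
                  pendant_mass = 0)
  core <- igraph::induced_subgraph(subgraph,
                                   which(igraph::coreness(subgraph) >= 2))
  metrics$pendant_mass <- if (n) 1 - igraph::vcount(core) / n else 0
  if (igraph::vcount(core) >= 8) {
    g8 <- igraph::girth(core)$girth
    if (is.finite(g8) && g8 >= 8) metrics$cycle_flag <- TRUE
  }
  shape <- if (n < 10) "amorphous"
    else if (metrics$cycle_flag) "circle"
    else if (metrics$normalized_diameter >= diam_min) "line"
    else if (metrics$hub_dominance >= hub_min) "star"
    else if (metrics$pendant_mass >= pendant_min &&
             igraph::vcount(core) >= 3) "ray"
    else "amorphous"
  structure(list(shape = shape, metrics = metrics), class = "shape_call")
}

#' Summarize repeat composition across annotated clusters
#'
#' Per-category genome percentage (sum of cluster proportions), the
#' cluster-count and top-N counters from the cluster table, and the
#' read-weighted mean GC of annotated clusters.
#'
#' @param cluster_table a \code{cluster_table}.
#' @param calls data.frame with \code{cluster_id} and \code{category}
#'   covering every tabled cluster.
#' @param gc_per_cluster named numeric (by cluster id) GC fractions, or
#'   NULL.
#' @return a \code{composition_summary}: list with
#'   \code{category_percent}, \code{clustered_percent},
#'   \code{n_at_thresholds}, \code{top_n_cumulative_percent},
#'   \code{gc_percent}.
#' @export
summarize_composition <- function(cluster_table, calls, gc_per_cluster = NULL) {
  missing <- setdiff(cluster_table$cluster_id, calls$cluster_id)
  if (length(missing))
    stop("missing superfamily call for cluster(s): ",
         paste(missing, collapse = ", "))
  cat_of <- stats::setNames(calls$category, calls$cluster_id)
  tabcat <- cat_of[as.character(cluster_table$cluster_id)]
  cats <- c("Gypsy", "Copia", "LINE", "DNA_transposon", "rDNA",
            "tandem/satellite", "unclassified")
  pct <- vapply(cats, function(ct)
    100 * sum(cluster_table$proportion[tabcat == ct]), numeric(1))
  gc_pct <- NA_real_
  if (!is.null(gc_per_cluster)) {
    w <- cluster_table$n_reads
    gcv <- gc_per_cluster[as.character(cluster_table$cluster_id)]
    ok <- !is.na(gcv)
    if (any(ok)) gc_pct <- 100 * sum(w[ok] * gcv[ok]) / sum(w[ok])
  }
  structure(list(category_percent = pct,
                 clustered_percent = 100 * sum(cluster_table$proportion),
                 n_at_thresholds = attr(cluster_table, "n_at_thresholds"),
                 top_n_cumulative_percent =
                   100 * attr(cluster_table, "top_n_cumulative"),
                 gc_percent = gc_pct),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Repeat composition (% of reads entered):\n")
  for (nm in names(x$category_percent))
    cat(sprintf("  %-18s %6.2f%%\n", nm, x$category_percent[nm]))
  cat(sprintf("  clustered total    %6.2f%%\n", x$clustered_percent))
  if (!is.na(x$gc_percent))
    cat(sprintf("  GC of annotated clusters: %.2f%%\n", x$gc_percent))
  invisible(x)
}
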