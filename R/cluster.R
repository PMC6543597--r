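#' Partition reads into repeat-family clusters
#'
#' Builds the read-overlap graph from qualifying edges and partitions it:
#' connected components first, then, for large sparse components whose
#' density suggests fused communities joined by "bridge" reads,
#' a deterministic greedy-modularity refinement. Reads participating in
#' no edge become singletons: excluded from cluster rows but retained in
#' the denominator of genome proportions. Cluster ids are ranked by size
#' (descending, ties by smallest member id), 1-based, following the
#' CL-number convention.
#'
#' @param edges an \code{overlap_edges} data.frame (or any data.frame
#'   with \code{read_a}, \code{read_b}).
#' @param read_ids character vector of all read ids entered (defines the
#'   denominator); defaults to the ids recorded on \code{edges}.
#' @param refine_density component density below which refinement is
#'   attempted (default 0.05).
#' @param refine_size component size above which refinement is attempted
#'   (default 100).
#' @param peripheral_frac,peripheral_min_size repeat-family clusters are
#'   orders of magnitude denser than their periphery: reads straddling
#'   an insertion junction carry less than a qualifying overlap of
#'   family sequence and attach only through a handful of same-junction
#'   partners, dragging flanking single-copy reads with them. In
#'   clusters larger than \code{peripheral_min_size}, members whose
#'   within-cluster degree falls below \code{max(3, peripheral_frac *
#'   median degree)} are returned to the unclustered pool (still counted
#'   in the denominator). Set \code{peripheral_frac = 0} to disable.
#' @param merge_min_cross,merge_frac after modularity splitting, two
#'   communities are re-merged when the number of edges between them is
#'   at least \code{max(merge_min_cross, merge_frac * smaller community
#'   size)}: a genuine repeat family cut through a thick seam (e.g. the
#'   LTR/internal junction of a retroelement, or one arc of a
#'   tandem-repeat ring) is reconnected by hundreds of read overlaps,
#'   whereas the thin chance-adjacency bridges between a repeat and
#'   flanking single-copy sequence are not.
#' @return a \code{read_clustering}: list with \code{clusters} (list of
#'   member-id character vectors, ranked), \code{membership} (named
#'   integer; NA for singletons), \code{singletons}, \code{graph}
#'   (igraph), \code{n_reads}.
#' @export
cluster_reads <- function(edges, read_ids = attr(edges, "read_ids"),
                          refine_density = 0.05, refine_size = 100L,
                          merge_min_cross = 50L, merge_frac = 0.2,
                          peripheral_frac = 0.05, peripheral_min_size = 50L) {
  if (is.null(read_ids))
    read_ids <- unique(c(edges$read_a, edges$read_b))
  stopifnot(all(edges$read_a %in% read_ids), all(edges$read_b %in% read_ids))
  # a pair may qualify on both strands; keep its best edge
  if (nrow(edges)) {
    ord <- order(edges$read_a, edges$read_b, -edges$identity, -edges$overlap)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(edges[, c("read_a", "read_b")]), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$read_a, to = edges$read_b,
               weight = edges$identity, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = read_ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  member_of <- rep(NA_integer_, length(read_ids))
  names(member_of) <- read_ids
  next_id <- 0L
  groups <- list()
  for (ci in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == ci]
    if (length(vs) == 1L) next # singleton
    sub <- igraph::induced_subgraph(g, vs)
    dens <- igraph::edge_density(sub)
    if (length(vs) > refine_size && dens < refine_density) {
      cm <- igraph::cluster_fast_greedy(sub)
      mem <- igraph::membership(cm)
      mem <- merge_thick_seams(sub, mem, merge_min_cross, merge_frac)
      for (k in sort(unique(mem))) {
        next_id <- next_id + 1L
        groups[[next_id]] <- sort(names(mem)[mem == k])
      }
    } else {
      next_id <- next_id + 1L
      groups[[next_id]] <- sort(vs)
    }
  }
  # prune the low-degree periphery of large clusters
  if (peripheral_frac > 0 && length(groups)) {
    groups <- lapply(groups, function(vs) {
      if (length(vs) <= peripheral_min_size) return(vs)
      deg <- igraph::degree(igraph::induced_subgraph(g, vs))
      thr <- max(3, peripheral_frac * stats::median(deg))
      keep <- sort(names(deg)[deg >= thr])
      if (length(keep) >= 2) keep else vs
    })
    groups <- groups[vapply(groups, length, integer(1)) >= 2]
  }
  # rank by size descending, ties by smallest member id
  if (length(groups)) {
    ord <- order(-vapply(groups, length, integer(1)),
                 vapply(groups, `[`, "", 1))
    groups <- groups[ord]
    for (i in seq_along(groups)) member_of[groups[[i]]] <- i
  }
  structure(list(clusters = groups, membership = member_of,
                 singletons = read_ids[is.na(member_of)],
                 graph = g, n_reads = length(read_ids)),
            class = "read_clustering")
}

## Re-merge modularity communities joined by a thick seam of edges.
## Iterates to a fixed point; deterministic (pairs processed in order of
## decreasing cross-edge count, ties by community id).
merge_thick_seams <- function(sub, mem, merge_min_cross, merge_frac) {
  el <- igraph::as_edgelist(sub, names = TRUE)
  repeat {
    ca <- mem[el[, 1]]
    cb <- mem[el[, 2]]
    cross <- ca != cb
    if (!any(cross)) break
    key <- paste(pmin(ca[cross], cb[cross]), pmax(ca[cross], cb[cross]))
    tab <- sort(table(key), decreasing = TRUE)
    sizes <- table(mem)
    merged <- FALSE
    for (i in seq_along(tab)) {
      uv <- as.integer(strsplit(names(tab)[i], " ")[[1]])
      thr <- max(merge_min_cross,
                 merge_frac * min(sizes[as.character(uv)]))
      if (tab[i] >= thr) {
        mem[mem == uv[2]] <- uv[1]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  mem
}

#' @export
print.read_clustering <- function(x, ...) {
  cat(sprintf("read_clustering: %d reads, %d clusters, %d singletons\n",
              x$n_reads, length(x$clusters), length(x$singletons)))
  invisible(x)
}

#' Tabulate clusters with genome proportions
#'
#' One row per cluster, sorted by proportion descending, with the
#' summary counters of a composition table: number of clusters at or
#' above each proportion threshold and the cumulative proportion of the
#' top clusters. The denominator is all reads entered into clustering,
#' singletons included.
#'
#' @param clustering a \code{read_clustering}.
#' @param total_reads denominator; defaults to reads entered.
#' @param thresholds proportion thresholds counted (defaults 0.0001 and
#'   0.01, i.e. the ">= 0.01\%" and ">= 1\%" counters).
#' @param top_n clusters in the cumulative-proportion counter
#'   (default 15).
#' @return data.frame of class \code{cluster_table}: \code{cluster_id},
#'   \code{label}, \code{n_reads}, \code{proportion}; attributes
#'   \code{n_at_thresholds}, \code{top_n_cumulative},
#'   \code{singleton_proportion}, \code{total_reads}.
#' @export
make_cluster_table <- function(clustering, total_reads = clustering$n_reads,
                               thresholds = c(1e-4, 1e-2), top_n = 15L) {
  if (total_reads <= 0) stop("total_reads must be positive")
  sizes <- vapply(clustering$clusters, length, integer(1))
  if (total_reads < sum(sizes))
    stop("total_reads smaller than clustered reads")
  df <- data.frame(cluster_id = seq_along(sizes),
                   label = sprintf("CL%d", seq_along(sizes)),
                   n_reads = sizes,
                   proportion = sizes / total_reads,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$proportion, df$cluster_id), , drop = FALSE]
  rownames(df) <- NULL
  n_at <- vapply(thresholds, function(t) sum(df$proportion >= t), integer(1))
  names(n_at) <- paste0(">=", thresholds)
  structure(df, class = c("cluster_table", "data.frame"),
            n_at_thresholds = n_at,
            top_n = as.integer(top_n),
            top_n_cumulative = sum(utils::head(df$proportion, top_n)),
            singleton_proportion = length(clustering$singletons) / total_reads,
            total_reads = total_reads)
}

#' First-order neighbour graph between clusters
#'
#' Nodes are clusters; an edge's weight counts the read pairs whose two
#' mates fall in different clusters, plus any supplied sub-threshold
#' read-pair similarities mapped to cluster pairs. Clusters with zero
#' neighbours are flagged probe-eligible (suitable as discrete FISH
#' probes).
#'
#' @param clustering a \code{read_clustering} whose read ids end in
#'   \code{/1} or \code{/2}.
#' @param sub_threshold data.frame with columns \code{read_a},
#'   \code{read_b} of read pairs similar below the edge criterion, or
#'   NULL.
#' @return a \code{cluster_neighbour_graph}: list with \code{graph}
#'   (igraph, weighted), \code{neighbour_count} (named integer per
#'   cluster id), \code{probe_eligible} (cluster ids with 0 neighbours).
#' @export
cluster_neighbours <- function(clustering, sub_threshold = NULL) {
  mem <- clustering$membership
  ids <- names(mem)
  pair_df <- function(a, b) {
    ca <- mem[a]; cb <- mem[b]
    keep <- !is.na(ca) & !is.na(cb) & ca != cb
    if (!any(keep)) return(NULL)
    data.frame(x = pmin(ca[keep], cb[keep]), y = pmax(ca[keep], cb[keep]))
  }
  m1 <- ids[grepl("/1$", ids)]
  m2 <- mate_of(m1)
  links <- pair_df(m1[m2 %in% ids], m2[m2 %in% ids])
  if (!is.null(sub_threshold) && nrow(sub_threshold))
    links <- rbind(links, pair_df(sub_threshold$read_a, sub_threshold$read_b))
  ncl <- length(clustering$clusters)
  g <- igraph::make_empty_graph(n = ncl, directed = FALSE)
  igraph::V(g)$name <- sprintf("CL%d", seq_len(ncl))
  if (!is.null(links) && nrow(links)) {
    agg <- stats::aggregate(list(weight = rep(1L, nrow(links))),
                            by = list(x = links$x, y = links$y), FUN = sum)
    g <- igraph::add_edges(g, rbind(agg$x, agg$y))
    igraph::E(g)$weight <- agg$weight
  }
  deg <- igraph::degree(g)
  structure(list(graph = g,
                 neighbour_count = stats::setNames(as.integer(deg),
                                                   igraph::V(g)$name),
                 probe_eligible = which(deg == 0)),
            class = "cluster_neighbour_graph")
}

#' Subgraph of one cluster's overlap graph
#'
#' @param clustering a \code{read_clustering}.
#' @param cluster_id 1-based cluster id.
#' @return igraph subgraph over the cluster's member reads.
#' @export
cluster_subgraph <- function(clustering, cluster_id) {
  igraph::induced_subgraph(clustering$graph,
                           clustering$clusters[[cluster_id]])
}
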