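#!/usr/bin/env Rscript

# Stage 3: graph-based read clustering and cluster annotation.
#
# Builds the read-overlap graph (edges: overlaps covering >= 50% of the
# shorter read at >= 90% identity, either strand), partitions it into
# repeat-family clusters, assembles a consensus per sizeable cluster,
# scans the consensi against the bundled domain exemplar library, and
# classifies each cluster (Gypsy / Copia / DNA transposon / rDNA /
# tandem-satellite / unclassified) plus its cluster-graph shape.
#
# Reads results/simulation/; writes results/clusters/: membership,
# cluster table, neighbour counts, per-cluster consensus FASTA,
# annotation and composition tables.

suppressPackageStartupMessages(library(repeatscape))
`%||%` <- function(a, b) if (is.null(a)) b else a

sim_dir <- "results/simulation"
out <- "results/clusters"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fq <- list.files(sim_dir, pattern = "^sample_.*\\.fastq$", full.names = TRUE)
reads <- unlist(lapply(fq, read_sequences))
cat(sprintf("clustering %d reads...\n", length(reads)))

edges <- find_overlaps(reads)
cl <- cluster_reads(edges)
print(cl)
ct <- make_cluster_table(cl)
nb <- cluster_neighbours(cl)

utils::write.table(
  data.frame(read_id = names(cl$membership), cluster = cl$membership),
  file.path(out, "membership.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(as.data.frame(ct), file.path(out, "cluster_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(cluster = names(nb$neighbour_count),
             neighbours = nb$neighbour_count),
  file.path(out, "neighbours.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
igraph::write_graph(nb$graph, file.path(out, "neighbour_graph.graphml"),
                    format = "graphml")

lib_ex <- default_exemplar_library()
big <- ct$cluster_id[ct$proportion >= 0.005]
cat(sprintf("annotating %d clusters at >= 0.5%% of reads\n", length(big)))
rows <- list()
cons_set <- character()
supp_rows <- list()
for (cid in big) {
  cons <- build_consensus(reads[cl$clusters[[cid]]])
  cons_set[sprintf("CL%d", cid)] <- cons$sequence
  supp_rows[[length(supp_rows) + 1L]] <- data.frame(
    cluster = cid, length = nchar(cons$sequence),
    mean_support = round(mean(cons$support), 1))
  per <- detect_periodicity(cons)
  call <- classify_superfamily(scan_domains(cons, lib_ex), per)
  shape <- classify_shape(cluster_subgraph(cl, cid))
  rows[[length(rows) + 1L]] <- data.frame(
    cluster = cid, proportion = ct$proportion[ct$cluster_id == cid],
    category = call$category, shape = shape$shape,
    fundamental = per$fundamental_period %||% NA,
    hor = per$hor_period %||% NA,
    gc = round(gc_content(reads[cl$clusters[[cid]]]), 4))
}
ann <- do.call(rbind, rows)
print(ann)
utils::write.table(ann, file.path(out, "annotation.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
Biostrings::writeXStringSet(Biostrings::DNAStringSet(cons_set),
                            file.path(out, "consensus.fasta"), width = 80L)
utils::write.table(do.call(rbind, supp_rows),
                   file.path(out, "consensus_stats.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

calls <- data.frame(cluster_id = ct$cluster_id,
                    category = ifelse(ct$cluster_id %in% ann$cluster,
                                      ann$category[match(ct$cluster_id,
                                                         ann$cluster)],
                                      "unclassified"))
comp <- summarize_composition(ct, calls)
print(comp)
cat("\nwrote", out, "\n")
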