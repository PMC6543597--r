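lib_ex <- make_exemplar_library()

test_that("domain scanning recovers planted exemplars with coordinates", {
  set.seed(91)
  rt <- lib_ex$sequence[lib_ex$domain_id == "RT"]
  cons <- paste0(rand_dna(500), rt, rand_dna(300))
  hits <- scan_domains(cons, lib_ex)
  rt_hit <- hits[hits$domain_id == "RT", ]
  expect_identical(nrow(rt_hit), 1L)
  expect_identical(rt_hit$start, 500L)
  expect_identical(rt_hit$end, 500L + nchar(rt))
  expect_identical(rt_hit$strand, "+")
  expect_identical(rt_hit$identity, 1)

  # reverse complement of an exemplar hits on the minus strand
  consm <- paste0(rand_dna(200), revcomp(rt), rand_dna(200))
  hm <- scan_domains(consm, lib_ex)
  rt_m <- hm[hm$domain_id == "RT", ]
  expect_identical(rt_m$strand, "-")
  expect_identical(rt_m$start, 200L)

  expect_error(scan_domains(cons, lib_ex[0, ]), "empty")
})

test_that("random sequence yields no domain hits at scan thresholds", {
  set.seed(92)
  for (i in 1:10) {
    h <- scan_domains(rand_dna(1000), lib_ex)
    expect_identical(nrow(h), 0L)
  }
})

test_that("domain order decides Gypsy versus Copia", {
  mk_hits <- function(ids, starts, lens = rep(300L, length(ids)),
                      strand = "+") {
    structure(data.frame(domain_id = ids, start = starts,
                         end = starts + lens, strand = strand,
                         identity = 0.95, coverage = 1,
                         stringsAsFactors = FALSE),
              class = c("domain_hits", "data.frame"))
  }
  expect_identical(
    classify_superfamily(mk_hits(c("RT", "RH", "INT"),
                                 c(100L, 450L, 650L)))$category, "Gypsy")
  expect_identical(
    classify_superfamily(mk_hits(c("INT", "RT", "RH"),
                                 c(100L, 400L, 750L)))$category, "Copia")
  # same order seen on the minus strand normalizes to the same call
  expect_identical(
    classify_superfamily(mk_hits(c("INT", "RH", "RT"),
                                 c(100L, 500L, 800L),
                                 strand = "-"))$category, "Gypsy")
  # duplicated domain with conflicting order -> unclassified, no error
  dup <- mk_hits(c("RT", "RH", "INT", "RT"), c(100L, 450L, 650L, 1000L))
  out <- classify_superfamily(dup)
  expect_identical(out$category, "unclassified")
  expect_match(out$note, "conflicting")

  # other evidence classes
  expect_identical(
    classify_superfamily(mk_hits("TRANSPOSASE", 100L))$category,
    "DNA_transposon")
  expect_identical(
    classify_superfamily(mk_hits("rDNA_18S", 0L, 1811L))$category, "rDNA")
  expect_true(classify_superfamily(mk_hits(c("RT", "RH"),
                                           c(0L, 400L)))$low_confidence)
  expect_identical(
    classify_superfamily(NULL, periodicity = "simple_tandem")$category,
    "tandem/satellite")
  expect_identical(classify_superfamily(NULL)$category, "unclassified")
})

test_that("classifying a consensus and its reverse complement agree", {
  set.seed(93)
  gy <- repeat_family_spec("g", "LTR_retro",
                           domain_order = c("RT", "RH", "INT"),
                           copies = c(A = 1L), template_divergence = 0.08)
  tmpl <- build_repeat_library(list(gy), seed = 94, library = lib_ex)$g$sequence
  c1 <- classify_superfamily(scan_domains(tmpl, lib_ex))
  c2 <- classify_superfamily(scan_domains(revcomp(tmpl), lib_ex))
  expect_identical(c1$category, "Gypsy")
  expect_identical(c2$category, "Gypsy")
})

test_that("constructed graphs classify to their textbook shapes", {
  expect_identical(classify_shape(igraph::make_ring(20))$shape, "circle")
  expect_identical(classify_shape(igraph::make_star(31, mode = "undirected"))$shape,
                   "star")
  expect_identical(classify_shape(igraph::make_ring(30, circular = FALSE))$shape,
                   "line")
  expect_identical(classify_shape(igraph::make_ring(5))$shape, "amorphous")
  expect_identical(classify_shape(igraph::make_full_graph(20))$shape,
                   "amorphous")
  # ray: a dense core with long pendant paths hanging off it
  core <- igraph::make_full_graph(12)
  ray <- igraph::add_vertices(core, 8)
  ray <- igraph::add_edges(ray, c(1, 13, 13, 14, 14, 15, 15, 16,
                                  2, 17, 17, 18, 18, 19, 19, 20))
  expect_identical(classify_shape(ray)$shape, "ray")
})

test_that("shape rules are mutually exclusive and total", {
  set.seed(95)
  shapes <- c("star", "ray", "circle", "line", "amorphous")
  for (i in 1:20) {
    g <- igraph::sample_gnp(sample(10:60, 1), stats::runif(1, 0.05, 0.6))
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    g <- igraph::induced_subgraph(g, which(comp$membership == big))
    s <- classify_shape(g)
    expect_identical(length(s$shape), 1L)
    expect_true(s$shape %in% shapes)
  }
})

test_that("composition summaries aggregate category percentages exactly", {
  fake <- structure(list(
    clusters = list(paste0("a", 1:30), paste0("b", 1:10), paste0("c", 1:10)),
    singletons = paste0("u", 1:50), n_reads = 100L),
    class = "read_clustering")
  ct <- make_cluster_table(fake)
  calls <- data.frame(cluster_id = 1:3,
                      category = c("Gypsy", "Gypsy", "Copia"))
  cs <- summarize_composition(ct, calls,
                              gc_per_cluster = c(`1` = 0.5, `2` = 0.4,
                                                 `3` = 0.3))
  expect_identical(unname(cs$category_percent["Gypsy"]), 40)
  expect_identical(unname(cs$category_percent["Copia"]), 10)
  expect_identical(cs$clustered_percent, 50)
  # read-weighted GC over annotated clusters
  expect_equal(cs$gc_percent, 100 * (30 * 0.5 + 10 * 0.4 + 10 * 0.3) / 50)

  # all-unclassified -> every named category at zero
  calls0 <- data.frame(cluster_id = 1:3, category = "unclassified")
  cs0 <- summarize_composition(ct, calls0)
  expect_true(all(cs0$category_percent[c("Gypsy", "Copia", "LINE")] == 0))

  expect_error(summarize_composition(ct, calls[1:2, ]), "missing.*3")

  # invariant to cluster id relabeling
  perm <- calls[c(3, 1, 2), ]
  expect_identical(summarize_composition(ct, perm)$category_percent,
                   cs$category_percent)
})
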