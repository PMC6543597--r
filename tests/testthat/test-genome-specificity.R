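test_that("read mapping counts exact, reverse, and no spurious matches", {
  set.seed(131)
  frag <- rand_dna(400)
  reads <- c(`a/1` = frag,                        # identical to fragment
             `b/1` = revcomp(substr(frag, 51, 350)), # rc of a subsequence
             `c/1` = rand_dna(300),               # unrelated
             `d/1` = substr(frag, 101, 200))      # fully contained
  n <- map_reads(reads, frag)
  mapped <- attr(n, "mapped")
  expect_identical(unname(mapped), c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(as.integer(n), 3L)

  # empirical null: random reads never map
  for (i in 1:10)
    expect_identical(as.integer(map_reads(c(`x/1` = rand_dna(250)), frag)), 0L)

  expect_error(map_reads(reads, ""), "empty")
  expect_error(map_reads(reads, "ACGTACGTACGT"), ">= 30")
})

test_that("copies_per_1C applies the base-normalized estimator", {
  expect_identical(copies_per_1C(0, 250, 150, 5), 0)
  expect_identical(copies_per_1C(300, 250, 150, 5), 300 * 250 / (150 * 5))
  expect_identical(copies_per_1C(300, 250, 150, 5, mode = "read"), 60)
  expect_error(copies_per_1C(10, 250, 150, 0), "positive")
  expect_error(copies_per_1C(-1, 250, 150, 5), ">= 0")
})

test_that("a planted 100-copy family is quantified within ten percent", {
  sim <- sim_satellite_readset(150L, 100L, seed = 141, background = 40000L)
  rs <- sim$reads
  frag <- sim$library$sat$sequence # the 150 bp monomer itself
  n <- map_reads(rs, frag)
  est <- copies_per_1C(as.integer(n), rs$read_length, nchar(frag),
                       rs$genome_equivalents)
  expect_lt(abs(est - 100) / 100, 0.10)

  # coverage invariance: doubling coverage moves the estimate by < 5%.
  # Each estimate is averaged over replicate read simulations of the
  # same genome so that read-sampling noise (binomial, ~3.5% per run at
  # this depth) does not dominate the comparison.
  g <- sim$genome
  est_at <- function(cov, seeds) {
    mean(vapply(seeds, function(s) {
      r <- simulate_reads(g, read_sim_spec(coverage = cov), seed = s)
      copies_per_1C(as.integer(map_reads(r, frag)), r$read_length,
                    nchar(frag), r$genome_equivalents)
    }, numeric(1)))
  }
  est5 <- est_at(5, 241:245)
  est10 <- est_at(10, 341:345)
  expect_lt(abs(est10 - est5) / est5, 0.05)
})

test_that("specificity categories follow the alpha/floor rule", {
  expect_identical(
    classify_specificity(c(A = 1000, C = 5, D = 5))$category, "A-specific")
  expect_identical(
    classify_specificity(c(A = 800, C = 900, D = 10),
                         categories = list("A", "C", "D", c("A", "C"),
                                           c("A", "C", "D")))$category,
    "A+C-specific")
  expect_identical(
    classify_specificity(c(A = 500, C = 520, D = 480))$category,
    "all-genomes")
  expect_identical(
    classify_specificity(c(A = 600, C = 2, D = 130))$category,
    "A+D-specific")
  # everything below the floor: explicit undetected state, never forced
  und <- classify_specificity(c(A = 3, C = 2, D = 1))
  expect_identical(und$category, "undetected")
  expect_identical(und$evidence, "all samples below detection floor")
  # a set outside the configured categories lands on its smallest
  # superset with a warning (the C+D asymmetry stays observable)
  warned <- classify_specificity(c(A = 2, C = 700, D = 650))
  expect_identical(warned$category, "all-genomes")
  expect_true(warned$warning_flag)
  expect_error(classify_specificity(c(A = 5)), ">= 2")
})

test_that("specificity calls are equivariant under label permutation", {
  cp <- c(A = 900, C = 40, D = 700)
  cats <- list("A", "C", "D", c("A", "D"), c("A", "C", "D"))
  perm <- c(A = "C", C = "D", D = "A")
  cp2 <- stats::setNames(cp, perm[names(cp)])
  cats2 <- lapply(cats, function(s) unname(perm[s]))
  call1 <- classify_specificity(cp, categories = cats)
  call2 <- classify_specificity(cp2, categories = cats2)
  expect_identical(sort(unname(perm[call1$qualifying])),
                   sort(call2$qualifying))
})

test_that("all five genome-specificity categories are recovered from reads", {
  # one family per category on a small A/C/D hexaploid; fragments are
  # the family templates (tiled for short monomers), mapping each
  # subgenome's sample separately
  fams <- list(
    repeat_family_spec("fC", "satellite", monomer_length = 43L,
                       copies = c(A = 0L, C = 120L, D = 0L), divergence = 0.02),
    repeat_family_spec("fA", "satellite", monomer_length = 150L,
                       copies = c(A = 40L, C = 0L, D = 0L), divergence = 0.02),
    repeat_family_spec("fD", "satellite", monomer_length = 340L,
                       copies = c(A = 0L, C = 0L, D = 15L), divergence = 0.02),
    repeat_family_spec("fAD", "satellite", monomer_length = 360L,
                       copies = c(A = 12L, C = 0L, D = 12L), divergence = 0.02),
    repeat_family_spec("fAll", "satellite", monomer_length = 200L,
                       copies = c(A = 25L, C = 25L, D = 25L), divergence = 0.02))
  lib <- build_repeat_library(fams, seed = 151)
  subg <- list(subgenome_spec("A", 30000L), subgenome_spec("C", 30000L),
               subgenome_spec("D", 30000L))
  g <- assemble_genome(subg, lib, seed = 152)
  samples <- lapply(names(g$sequences), function(sg)
    simulate_reads(g$sequences[sg], read_sim_spec(coverage = 5),
                   seed = 153 + match(sg, names(g$sequences)),
                   stated_1C = nchar(g$sequences[[sg]])))
  names(samples) <- names(g$sequences)
  tile <- function(s, min_len) strrep(s, ceiling(min_len / nchar(s)))
  want <- c(fC = "C-specific", fA = "A-specific", fD = "D-specific",
            fAD = "A+D-specific", fAll = "all-genomes")
  for (fam in names(want)) {
    frag <- tile(lib[[fam]]$sequence, 300L)
    cp <- vapply(samples, function(rs)
      copies_per_1C(as.integer(map_reads(rs, frag)), rs$read_length,
                    nchar(frag), rs$genome_equivalents), numeric(1))
    expect_identical(classify_specificity(cp)$category, unname(want[fam]))
  }
})

test_that("probe selection honours neighbours, length, and complexity", {
  fake_ct <- structure(
    data.frame(cluster_id = 1:3, label = paste0("CL", 1:3),
               n_reads = c(50L, 40L, 30L), proportion = c(0.5, 0.4, 0.3)),
    class = c("cluster_table", "data.frame"))
  g <- igraph::make_empty_graph(n = 3, directed = FALSE)
  igraph::V(g)$name <- paste0("CL", 1:3)
  g <- igraph::add_edges(g, c(2, 3, 2, 1, 2, 3, 2, 1, 2, 3))
  fake_nb <- structure(list(
    graph = g,
    neighbour_count = c(CL1 = 2L, CL2 = 5L, CL3 = 3L),
    probe_eligible = integer(0)), class = "cluster_neighbour_graph")
  set.seed(161)
  consensi <- list(`1` = rand_dna(400), `2` = rand_dna(400),
                   `3` = strrep("A", 400))
  # cluster 2 exceeds max_neighbours; cluster 3 fails the complexity filter
  pc <- select_probes(fake_ct, fake_nb, consensi, max_neighbours = 2L)
  expect_identical(pc$cluster_id, 1L)
  expect_identical(pc$length, 400L)
  # homopolymer consensus rejected even when neighbours allow it
  pc2 <- select_probes(fake_ct, fake_nb, consensi, max_neighbours = 10L)
  expect_false(3L %in% pc2$cluster_id)
  # too-short consensus excluded by the length range
  pc3 <- select_probes(fake_ct, fake_nb, list(`1` = rand_dna(50)),
                       max_neighbours = 10L)
  expect_identical(nrow(pc3), 0L)
})
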