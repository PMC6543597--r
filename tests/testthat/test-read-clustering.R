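test_that("the edge criterion is enforced on overlap and identity", {
  set.seed(61)
  r <- rand_dna(250)
  # identical reads: one edge, full overlap, identity 1
  e <- find_overlaps(c(a = r, b = r))
  expect_identical(nrow(e), 1L)
  expect_identical(e$overlap, 250L)
  expect_identical(e$identity, 1)

  # sharing only 100/250 bases (40% < 50%): no edge
  tmpl <- rand_dna(400)
  x <- substr(tmpl, 1, 250)
  y <- substr(tmpl, 151, 400)
  expect_identical(nrow(find_overlaps(c(a = x, b = y))), 0L)

  # both strand orientations are tested
  e2 <- find_overlaps(c(a = r, b = revcomp(r)))
  expect_identical(nrow(e2), 1L)
  expect_identical(e2$strand, "-")

  expect_error(find_overlaps(c(a = r, a = r)), "deduplicated")
})

test_that("threshold-straddling overlaps agree with a full DP oracle", {
  set.seed(62)
  # reads overlap by 150 of their 250 bp
  tmpl <- rand_dna(350)
  x <- substr(tmpl, 1, 250)
  y250 <- substr(tmpl, 101, 350)
  plant <- function(seq, n) {
    ch <- strsplit(seq, "")[[1]]
    pos <- sample(50:150, n) # inside the overlapping segment of y
    for (i in pos) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  y5 <- plant(y250, 5)   # identity 145/150 = 0.967 -> edge
  y20 <- plant(y250, 20) # identity 130/150 = 0.867 -> no edge
  expect_identical(nrow(find_overlaps(c(a = x, b = y5))), 1L)
  expect_identical(nrow(find_overlaps(c(a = x, b = y20))), 0L)

  # Biostrings ends-free DP oracle agrees (gap-free optimum under a
  # substitution-only model, enforced with prohibitive gap penalties)
  dp_identity <- function(p, s) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(p), Biostrings::DNAString(s), type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 10000, gapExtension = 10000)
    Biostrings::nmatch(aln) /
      (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln))
  }
  expect_gte(dp_identity(x, y5), 0.9)
  expect_lt(dp_identity(x, y20), 0.9)
})

test_that("connected components equal the exhaustive alignment oracle", {
  set.seed(63)
  # 80 short reads: some tiled from two templates, some random
  mk <- function(tmpl, n) {
    st <- sort(sample.int(nchar(tmpl) - 99, n))
    substring(tmpl, st, st + 99)
  }
  reads <- c(mk(rand_dna(400), 25), mk(rand_dna(400), 25),
             vapply(1:30, function(i) rand_dna(100), character(1)))
  flip <- seq(1, 80, by = 3)
  reads[flip] <- revcomp(reads[flip])
  names(reads) <- sprintf("r%02d", 1:80)

  edges <- find_overlaps(reads, seed_len = 12L, index_step = 1L)
  got <- paste(sort(paste(pmin(edges$read_a, edges$read_b),
                          pmax(edges$read_a, edges$read_b))))
  want <- character(0)
  for (i in 1:79) for (j in (i + 1):80) {
    if (oracle_pair_overlaps(reads[[i]], reads[[j]]))
      want <- c(want, paste(names(reads)[i], names(reads)[j]))
  }
  expect_setequal(got, sort(want))
})

test_that("clustering partitions reads with transitive components", {
  set.seed(64)
  tmpl <- rand_dna(500)
  reads <- c(a = substr(tmpl, 1, 250), b = substr(tmpl, 126, 375),
             c = substr(tmpl, 251, 500), d = rand_dna(250))
  cl <- cluster_reads(find_overlaps(reads))
  expect_identical(length(cl$clusters), 1L)
  expect_identical(cl$clusters[[1]], c("a", "b", "c"))
  expect_identical(cl$singletons, "d")

  # two families, no cross-family edges -> exactly two clusters
  f1 <- make_tandem_array(rand_dna(100), 8)
  f2 <- make_tandem_array(rand_dna(100), 8)
  r2 <- c(x1 = substr(f1, 1, 250), x2 = substr(f1, 301, 550),
          y1 = substr(f2, 1, 250), y2 = substr(f2, 301, 550))
  cl2 <- cluster_reads(find_overlaps(r2))
  expect_identical(length(cl2$clusters), 2L)
})

test_that("simulated two-family reads are recovered at high adjusted Rand index", {
  fam1 <- repeat_family_spec("f1", "satellite", monomer = rand_dna(300),
                             copies = c(A = 40L), divergence = 0.02)
  # second family: a 20%-diverged relative of the first monomer
  fam2 <- repeat_family_spec("f2", "satellite",
                             monomer = mutate_at(fam1$monomer, 0.20),
                             copies = c(A = 40L), divergence = 0.02)
  lib <- build_repeat_library(list(fam1, fam2), seed = 65)
  g <- assemble_genome(subgenome_spec("A", 25000L), lib, seed = 66)
  rs <- simulate_reads(g, read_sim_spec(coverage = 5), seed = 67)
  truth <- read_truth_family(names(rs$reads), g$truth)
  keep <- truth != "background"
  cl <- cluster_reads(find_overlaps(rs$reads[keep]))
  expect_gte(length(cl$clusters), 2L)
  lab <- cl$membership[names(rs$reads)[keep]]
  lab[is.na(lab)] <- -seq_len(sum(is.na(lab))) # singletons: own labels
  expect_gte(adjusted_rand(truth[keep], lab), 0.9)
})

test_that("cluster tables compute proportions and counters exactly", {
  fake <- structure(list(
    clusters = list(paste0("r", 1:30), paste0("s", 1:20), paste0("t", 1:10)),
    membership = NULL, singletons = paste0("u", 1:40), n_reads = 100L),
    class = "read_clustering")
  ct <- make_cluster_table(fake)
  expect_identical(ct$proportion, c(0.30, 0.20, 0.10))
  expect_identical(attr(ct, "top_n_cumulative"), 0.60)
  ct2 <- make_cluster_table(fake, top_n = 2L)
  expect_identical(attr(ct2, "top_n_cumulative"), 0.50)
  expect_identical(unname(attr(ct, "n_at_thresholds")), c(3L, 3L))
  expect_identical(attr(ct, "singleton_proportion"), 0.4)
  expect_error(make_cluster_table(fake, total_reads = 0), "positive")
  expect_error(make_cluster_table(fake, total_reads = 10), "smaller")

  # partition property: proportions plus singletons account for all reads
  expect_identical(sum(ct$proportion) + attr(ct, "singleton_proportion"), 1)
})

test_that("a planted family's cluster proportion tracks its base share", {
  sim <- sim_satellite_readset(150L, 80L, seed = 71, background = 100000L)
  truth <- unname(sim$genome$truth$family_proportion["sat"]) # ~0.107
  cl <- cluster_reads(find_overlaps(sim$reads))
  ct <- make_cluster_table(cl)
  # the satellite's cluster is the one holding most of its truth reads
  fam <- read_truth_family(names(sim$reads$reads), sim$genome$truth)
  sat_cl <- as.integer(names(which.max(
    table(cl$membership[names(sim$reads$reads)[fam == "sat"]]))))
  p <- ct$proportion[ct$cluster_id == sat_cl]
  expect_lt(abs(p - truth), 0.02)
})

test_that("mate pairs split across clusters define first-order neighbours", {
  # two separate families; no cross-cluster mates -> no neighbours
  f1 <- make_tandem_array(rand_dna(100), 8)
  f2 <- make_tandem_array(rand_dna(100), 8)
  reads <- c(`p1_000001_1/1` = substr(f1, 1, 250),
             `p1_000001_1/2` = substr(f1, 201, 450),
             `p2_000001_1/1` = substr(f2, 1, 250),
             `p2_000001_1/2` = substr(f2, 201, 450))
  cl <- cluster_reads(find_overlaps(reads))
  nb <- cluster_neighbours(cl)
  expect_identical(unname(nb$neighbour_count), c(0L, 0L))
  expect_identical(length(nb$probe_eligible), 2L)

  # one mate pair split across the clusters -> edge of weight 1
  reads2 <- c(reads,
              `px_000002_1/1` = substr(f1, 301, 550),
              `px_000002_1/2` = substr(f2, 301, 550))
  cl2 <- cluster_reads(find_overlaps(reads2))
  nb2 <- cluster_neighbours(cl2)
  expect_identical(unname(nb2$neighbour_count), c(1L, 1L))
  expect_identical(igraph::E(nb2$graph)$weight, 1L)
})

test_that("a retroelement nested in a satellite array links their clusters", {
  set.seed(72)
  # build the locus by hand: satellite array with an element inserted
  sat <- make_tandem_array(rand_dna(120), 60) # 7.2 kb
  elem <- rand_dna(2000)
  locus <- paste0(substr(sat, 1, 3600), elem, substr(sat, 3601, 7200))
  # 700 bp inserts leave a 200 bp gap between mates, so a pair can span
  # a junction with both reads cleanly on opposite sides
  rs <- simulate_reads(c(L = locus),
                       read_sim_spec(insert_length = 700L, coverage = 6),
                       seed = 73)
  # keep only pairs whose reads lie cleanly on one side of a junction,
  # so the mate links (not chimeric reads) connect the two clusters
  stems <- sub("/[12]$", "", names(rs$reads))
  fstart <- as.integer(sub(".*_", "", stems)) - 1L
  rstart <- ifelse(grepl("/1$", names(rs$reads)), fstart, fstart + 450L)
  straddles <- function(s) (s < 3600 & s + 250 > 3600) |
    (s < 5600 & s + 250 > 5600)
  bad_stems <- unique(stems[straddles(rstart)])
  reads <- rs$reads[!stems %in% bad_stems]
  cl <- cluster_reads(find_overlaps(reads))
  nb <- cluster_neighbours(cl)
  big <- order(-vapply(cl$clusters, length, integer(1)))[1:2]
  g <- nb$graph
  expect_true(igraph::are_adjacent(g, sprintf("CL%d", big[1]),
                                   sprintf("CL%d", big[2])))
})

test_that("clustering a half subsample moves the top proportion by little", {
  sim <- sim_satellite_readset(150L, 50L, seed = 81, background = 30000L)
  cl <- cluster_reads(find_overlaps(sim$reads))
  p_full <- make_cluster_table(cl)$proportion[1]
  stems <- unique(sub("/[12]$", "", names(sim$reads$reads)))
  set.seed(82)
  keep <- sample(stems, length(stems) %/% 2)
  sub <- sim$reads$reads[sub("/[12]$", "", names(sim$reads$reads)) %in% keep]
  p_half <- make_cluster_table(cluster_reads(find_overlaps(sub)))$proportion[1]
  expect_lt(abs(p_full - p_half), 0.03)
})
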