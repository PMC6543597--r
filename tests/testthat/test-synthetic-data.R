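test_that("repeat family and subgenome specs enforce their invariants", {
  expect_error(repeat_family_spec("x", "retro_thing", copies = c(A = 1L)),
               "unknown repeat kind")
  expect_error(repeat_family_spec("x", "LTR_retro", copies = c(A = 1L)),
               "domain_order")
  expect_error(repeat_family_spec("x", "satellite", monomer = "ACGTACG",
                                  copies = c(A = 1L)),
               ">= 10")
  expect_error(repeat_family_spec("x", "satellite", monomer_length = 50L,
                                  copies = c(A = 1L), divergence = 0.5),
               "divergence")
  inert <- repeat_family_spec("x", "satellite", monomer_length = 50L,
                              copies = c(A = 0L, C = 0L))
  expect_true(inert$inert)
  expect_error(subgenome_spec("A", 5000L), "10 kb")
  expect_error(subgenome_spec("A", 20000L, gc = 1.2), "gc")
  expect_error(read_sim_spec(read_length = 250L, insert_length = 200L),
               "insert_length")
  expect_error(read_sim_spec(error_rate = 0.2), "error_rate")
})

test_that("rDNA templates concatenate their components to the unit length", {
  spec <- repeat_family_spec("rdna45S", "rDNA", components = rdna_components,
                             copies = c(A = 1L))
  lib <- build_repeat_library(list(spec), seed = 7)
  expect_identical(lib$rdna45S$length, sum(rdna_components))
  expect_identical(lib$rdna45S$length, 9059L)
  # feature map covers the unit contiguously in the stated order
  f <- lib$rdna45S$features
  expect_identical(f$label, names(rdna_components))
  expect_identical(f$start, cumsum(c(0L, unname(rdna_components[-6]))))
  expect_identical(f$end - f$start, unname(rdna_components))
})

test_that("satellite and LTR templates are realized with exact coordinates", {
  sat <- repeat_family_spec("s", "satellite", monomer = rand_dna(43),
                            copies = c(A = 5L))
  lib <- build_repeat_library(list(sat), seed = 1)
  expect_identical(lib$s$length, 43L)
  expect_identical(nrow(lib$s$features), 1L)

  gy <- repeat_family_spec("g", "LTR_retro",
                           domain_order = c("RT", "RH", "INT"),
                           copies = c(A = 2L))
  lib2 <- build_repeat_library(list(gy), seed = 1)
  f <- lib2$g$features
  doms <- f[f$label %in% c("RT", "RH", "INT"), ]
  expect_identical(doms$label[order(doms$start)], c("RT", "RH", "INT"))
  # every feature's coordinates index the template exactly
  expect_true(all(doms$end <= lib2$g$length))

  cp <- repeat_family_spec("c", "LTR_retro",
                           domain_order = c("INT", "RT", "RH"),
                           copies = c(A = 1L))
  f2 <- build_repeat_library(list(cp), seed = 1)$c$features
  doms2 <- f2[f2$label %in% c("RT", "RH", "INT"), ]
  expect_identical(doms2$label[order(doms2$start)], c("INT", "RT", "RH"))
})

test_that("assembled genomes record exact truth proportions and copies", {
  # empty case
  g0 <- assemble_genome(subgenome_spec("A", 100000L),
                        build_repeat_library(list(), seed = 1), seed = 2)
  expect_identical(nchar(g0$sequences[["A"]]), 100000L)
  expect_identical(nrow(g0$truth$intervals), 0L)

  # one 10 kb array in 90 kb background -> proportion exactly 0.1
  sat <- repeat_family_spec("s", "satellite", monomer = rand_dna(100),
                            copies = c(A = 100L, C = 0L), divergence = 0)
  lib <- build_repeat_library(list(sat), seed = 3)
  g <- assemble_genome(list(subgenome_spec("A", 90000L),
                            subgenome_spec("C", 10000L)), lib, seed = 4)
  expect_identical(unname(g$truth$family_proportion["s"]),
                   10000 / (90000 + 10000 + 10000))
  expect_identical(unname(g$truth$true_copies$s["A"]), 100)
  expect_identical(unname(g$truth$true_copies$s["C"]), 0)

  # proportions recomputable exactly from the intervals / emitted BED
  iv <- g$truth$intervals
  expect_identical(sum(iv$end - iv$start) / g$truth$total_length,
                   unname(g$truth$family_proportion["s"]))
  dir <- withr::local_tempdir()
  write_genome(g, dir)
  bed <- rtracklayer::import.bed(file.path(dir, "truth.bed"))
  expect_identical(sum(BiocGenerics::width(bed)) / g$truth$total_length,
                   unname(g$truth$family_proportion["s"]))

  # intervals never overlap within a subgenome
  for (sg in unique(iv$subgenome)) {
    sub <- iv[iv$subgenome == sg, ]
    sub <- sub[order(sub$start), ]
    expect_true(all(diff(sub$start) >= head(sub$end - sub$start, -1)))
  }

  # insufficient space errors name family and subgenome
  big <- repeat_family_spec("huge", "satellite", monomer = rand_dna(500),
                            copies = c(A = 100L))
  expect_error(assemble_genome(subgenome_spec("A", 10000L),
                               build_repeat_library(list(big), seed = 1),
                               seed = 2),
               "huge.*A")
})

test_that("read simulation honours pair count, purity, and determinism", {
  genome <- c(G = rand_dna(1000))
  spec <- read_sim_spec(read_length = 100L, insert_length = 200L,
                        coverage = 5, error_rate = 0)
  rs <- simulate_reads(genome, spec, seed = 11)
  expect_identical(length(rs$reads), 2L * 25L) # round(5*1000/(2*100))

  # error-free reads are exact substrings of the genome or its revcomp
  fwd <- genome[["G"]]
  rev <- revcomp(fwd)
  hit <- vapply(rs$reads, function(r)
    grepl(r, fwd, fixed = TRUE) || grepl(r, rev, fixed = TRUE), logical(1))
  expect_true(all(hit))

  # same seed -> byte-identical FASTQ
  d <- withr::local_tempdir()
  write_read_fastq(simulate_reads(genome, spec, seed = 11),
                   file.path(d, "a"))
  write_read_fastq(simulate_reads(genome, spec, seed = 11),
                   file.path(d, "b"))
  for (m in 1:2)
    expect_identical(readLines(file.path(d, sprintf("a_%d.fastq", m))),
                     readLines(file.path(d, sprintf("b_%d.fastq", m))))

  expect_error(simulate_reads(genome, read_sim_spec(read_length = 100L,
                                                    insert_length = 2000L),
                              seed = 1),
               "insert")
})

test_that("mean read depth matches the requested coverage", {
  genome <- c(G = rand_dna(100000))
  rs <- simulate_reads(genome, read_sim_spec(coverage = 5), seed = 5)
  depth <- sum(nchar(rs$reads)) / 100000
  expect_lt(abs(depth - 5) / 5, 0.05)
})

test_that("planted copies diverge by the requested substitution fraction", {
  div <- 0.05
  sat <- repeat_family_spec("s", "satellite", monomer = rand_dna(400),
                            copies = c(A = 30L), divergence = div)
  lib <- build_repeat_library(list(sat), seed = 21)
  g <- assemble_genome(subgenome_spec("A", 20000L), lib, seed = 22)
  iv <- g$truth$intervals
  seqs <- substring(g$sequences[["A"]], iv$start + 1, iv$end)
  pick <- utils::combn(seq_len(10), 2)
  ident <- apply(pick, 2, function(p) {
    a <- utf8ToInt(seqs[p[1]]); b <- utf8ToInt(seqs[p[2]])
    mean(a == b)
  })
  # mean pairwise identity ~ (1 - div)^2 + div^2/3 ~ 1 - 2*div
  expect_lt(abs(mean(ident) - (1 - 2 * div)), 0.02)
})
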