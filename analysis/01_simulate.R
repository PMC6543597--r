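#!/usr/bin/env Rscript

# Stage 1: build the reference synthetic hexaploid and its read set.
#
# Three subgenomes (A/C/D, 100 kb background each at 43% GC) carry six
# planted repeat families: four satellites (43 bp C-specific, 150 bp
# A-specific, 340 bp D-specific, 360 bp shared A+D), a Gypsy-like LTR
# retroelement (RT-RH-INT) present in all subgenomes, and a Copia-like
# element (INT-RT-RH), with a genome-wide Gypsy:Copia base ratio of
# 2.5:1. Each subgenome is "sequenced" separately at 5x with 2 x 250 bp
# pairs from 500 bp inserts and 0.5% substitution error, emulating
# per-species whole-genome shotgun libraries.
#
# Outputs (results/simulation/): per-subgenome FASTA, truth BED/JSON,
# paired FASTQ per subgenome sample.

suppressPackageStartupMessages(library(repeatscape))

seed <- 101L
out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- hexaploid_demo_config(seed = seed)
lib <- build_repeat_library(cfg$families,
                            seed = repeatscape:::derive_seed(seed, "library"))
print(lib)
genome <- assemble_genome(cfg$subgenomes, lib,
                          seed = repeatscape:::derive_seed(seed, "genome"))
write_genome(genome, out)

cat("\nPlanted family proportions (of total genome bases):\n")
print(round(genome$truth$family_proportion, 4))

for (sg in names(genome$sequences)) {
  rs <- simulate_reads(genome$sequences[sg], cfg$read_sim,
                       seed = repeatscape:::derive_seed(seed,
                                                        paste0("reads_", sg)),
                       stated_1C = cfg$stated_1C[[sg]])
  write_read_fastq(rs, file.path(out, paste0("sample_", sg)))
  cat(sprintf("sample %s: %d reads, %.2f genome equivalents\n",
              sg, length(rs$reads), rs$genome_equivalents))
}
cat("\nwrote", out, "\n")
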