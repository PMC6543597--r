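# Shared fixture builders and independent oracles, all generated in code.

rdna_components <- c(ETS = 3197L, `18S` = 1811L, ITS1 = 260L,
                     `5.8S` = 168L, ITS2 = 216L, `26S` = 3407L)

rand_dna <- function(n, gc = 0.5) repeatscape:::random_dna(n, gc)

mutate_at <- function(seq, rate) repeatscape:::mutate_seq(seq, rate)

## Tandem array of n copies of a monomer, each copy independently
## mutated at per-copy divergence.
make_tandem_array <- function(monomer, n_copies, divergence = 0) {
  paste(vapply(seq_len(n_copies), function(i) mutate_at(monomer, divergence),
               character(1)), collapse = "")
}

## Higher-order dimer array: a monomer plus a diverged partner of equal
## length, tiled as a dimer with per-copy divergence.
make_hor_array <- function(monomer_len = 116L, partner_divergence = 0.08,
                           n_dimers = 50L, copy_divergence = 0.02) {
  m <- rand_dna(monomer_len)
  dimer <- paste0(m, mutate_at(m, partner_divergence))
  make_tandem_array(dimer, n_dimers, copy_divergence)
}

## Brute-force k-mer dictionary oracle: slide a window over every read,
## skip windows with non-ACGT, optionally merge strands.
oracle_kmers <- function(reads, k, canonical = TRUE) {
  counts <- new.env(hash = TRUE)
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      m <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", m)) next
      if (canonical) {
        rc <- repeatscape::revcomp(m)
        if (rc < m) m <- rc
      }
      counts[[m]] <- (counts[[m]] %||% 0) + 1
    }
  }
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Exhaustive all-offset overlap oracle for one read pair: evaluates
## every gap-free alignment offset on both strands (the optimal overlap
## alignment under a substitution-only model) and reports whether any
## qualifies under the edge criterion.
oracle_pair_overlaps <- function(x, y, min_frac = 0.5, min_id = 0.9) {
  xi <- utf8ToInt(x)
  qualify <- function(yc) {
    yi <- utf8ToInt(yc)
    n <- length(xi); m <- length(yi)
    eq <- outer(xi, yi, "==")
    d <- as.vector(row(eq) - col(eq))
    ms <- rowsum(as.numeric(eq), d)
    dv <- as.integer(rownames(ms))
    len <- pmin(n, m + dv) - pmax(0, dv)
    need <- ceiling(min_frac * min(n, m))
    any(len >= need & ms[, 1] / pmax(len, 1) >= min_id & len > 0)
  }
  qualify(y) || qualify(repeatscape::revcomp(y))
}

## Adjusted Rand index between two labelings (standard formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}

## True family of each simulated read, from the id-encoded origin.
read_truth_family <- function(read_ids, truth, read_length = 250L,
                              insert_length = 500L) {
  stem <- sub("/[12]$", "", read_ids)
  sg <- sub("_.*$", "", stem)
  fstart <- as.integer(sub(".*_", "", stem))
  start <- ifelse(grepl("/1$", read_ids), fstart,
                  fstart + insert_length - read_length) - 1L
  end <- start + read_length
  fam <- rep("background", length(read_ids))
  iv <- truth$intervals
  # merge contiguous per-copy intervals (tandem arrays) into blocks
  key <- paste(iv$subgenome, iv$family)
  blocks <- do.call(rbind, lapply(split(iv, key), function(d) {
    d <- d[order(d$start), ]
    grp <- cumsum(c(TRUE, d$start[-1] > d$end[-nrow(d)]))
    do.call(rbind, lapply(split(d, grp), function(b)
      data.frame(subgenome = b$subgenome[1], family = b$family[1],
                 start = min(b$start), end = max(b$end))))
  }))
  for (i in seq_len(NROW(blocks))) {
    ovl <- pmin(end, blocks$end[i]) - pmax(start, blocks$start[i])
    hit <- sg == blocks$subgenome[i] & ovl > read_length / 2
    fam[hit] <- blocks$family[i]
  }
  fam
}

## Small single-subgenome simulation used by several tests.
sim_satellite_readset <- function(monomer_len, n_copies, seed,
                                  background = 15000L, coverage = 5,
                                  divergence = 0.02, error_rate = 0.005) {
  fam <- repeat_family_spec("sat", "satellite", monomer_length = monomer_len,
                            copies = c(A = as.integer(n_copies)),
                            divergence = divergence)
  lib <- build_repeat_library(list(fam), seed = seed)
  g <- assemble_genome(subgenome_spec("A", background), lib, seed = seed + 1L)
  rs <- simulate_reads(g, read_sim_spec(coverage = coverage,
                                        error_rate = error_rate),
                       seed = seed + 2L)
  list(genome = g, reads = rs, library = lib)
}
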