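#' Assemble a multi-subgenome synthetic genome with planted repeats
#'
#' Builds one sequence per subgenome: a random background of the stated
#' length and GC content into which every requested repeat copy is
#' inserted at a random position, without overlaps. Satellite and rDNA
#' families are laid down as contiguous tandem arrays by default
#' (FISH-visible arrays are tens of kb); other kinds are dispersed, each
#' dispersed copy on a random strand. Every copy is independently
#' mutated at the family's per-copy divergence. Ground truth (intervals,
#' exact base proportions, copy counts) is recorded alongside.
#'
#' @param subgenomes list of \code{\link{subgenome_spec}}.
#' @param library a \code{repeat_library} from
#'   \code{\link{build_repeat_library}}.
#' @param seed integer seed.
#' @return list with \code{sequences} (named character vector, one per
#'   subgenome), \code{truth} (class \code{genome_truth}: \code{intervals}
#'   data.frame in 0-based half-open coordinates, \code{family_proportion},
#'   \code{true_copies}, \code{total_length}), and \code{subgenomes}.
#' @export
assemble_genome <- function(subgenomes, library, seed = 1L) {
  if (inherits(subgenomes, "subgenome_spec")) subgenomes <- list(subgenomes)
  labs <- vapply(subgenomes, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("subgenome labels must be unique")
  res <- with_seed(seed, {
    seqs <- character(length(subgenomes))
    names(seqs) <- labs
    iv <- list()
    for (si in seq_along(subgenomes)) {
      sg <- subgenomes[[si]]
      units <- list() # each: list(seq, family, copy_bounds data.frame)
      planted <- 0L
      for (tmpl in library) {
        cp <- tmpl$spec$copies
        ncop <- if (sg$label %in% names(cp)) cp[[sg$label]] else 0L
        if (is.na(ncop) || ncop == 0) next
        need <- ncop * tmpl$length
        if (planted + need > sg$background_length)
          stop("insufficient background space for family '", tmpl$name,
               "' in subgenome '", sg$label, "'")
        planted <- planted + need
        div <- tmpl$spec$divergence
        copies <- vapply(seq_len(ncop), function(i)
          mutate_seq(tmpl$sequence, div), character(1))
        if (tmpl$spec$array_mode == "tandem") {
          bounds <- data.frame(
            family = tmpl$name,
            rel_start = (seq_len(ncop) - 1L) * tmpl$length,
            rel_end = seq_len(ncop) * tmpl$length,
            strand = "+", stringsAsFactors = FALSE)
          units[[length(units) + 1L]] <-
            list(seq = paste(copies, collapse = ""), bounds = bounds)
        } else {
          for (i in seq_len(ncop)) {
            s <- copies[i]
            strand <- if (stats::runif(1) < 0.5) "+" else "-"
            if (strand == "-") s <- revcomp(s)
            units[[length(units) + 1L]] <- list(
              seq = s,
              bounds = data.frame(family = tmpl$name, rel_start = 0L,
                                  rel_end = tmpl$length, strand = strand,
                                  stringsAsFactors = FALSE))
          }
        }
      }
      bg <- random_dna(sg$background_length, sg$gc)
      nu <- length(units)
      if (nu == 0) {
        seqs[si] <- bg
        next
      }
      # random, order-shuffled insertion points in the background
      cuts <- sort(sample.int(sg$background_length + 1L, nu, replace = TRUE) - 1L)
      units <- units[sample.int(nu)]
      pieces <- character(2L * nu + 1L)
      prev <- 0L
      pos <- 0L
      sub_iv <- list()
      for (u in seq_len(nu)) {
        bgseg <- substr(bg, prev + 1L, cuts[u])
        pieces[2L * u - 1L] <- bgseg
        pos <- pos + nchar(bgseg)
        b <- units[[u]]$bounds
        b$start <- pos + b$rel_start
        b$end <- pos + b$rel_end
        sub_iv[[u]] <- b[, c("family", "start", "end", "strand")]
        pieces[2L * u] <- units[[u]]$seq
        pos <- pos + nchar(units[[u]]$seq)
        prev <- cuts[u]
      }
      pieces[2L * nu + 1L] <- substr(bg, prev + 1L, sg$background_length)
      seqs[si] <- paste(pieces, collapse = "")
      ivd <- do.call(rbind, sub_iv)
      ivd$subgenome <- sg$label
      iv[[length(iv) + 1L]] <- ivd
    }
    list(seqs = seqs, iv = iv)
  })
  intervals <- if (length(res$iv)) do.call(rbind, res$iv) else
    data.frame(family = character(), start = integer(), end = integer(),
               strand = character(), subgenome = character(),
               stringsAsFactors = FALSE)
  intervals <- intervals[, c("subgenome", "family", "start", "end", "strand")]
  total_length <- sum(nchar(res$seqs))
  fams <- vapply(library, `[[`, "", "name")
  planted_bases <- vapply(fams, function(f)
    sum(intervals$end[intervals$family == f] -
        intervals$start[intervals$family == f]), numeric(1))
  true_copies <- sapply(fams, function(f) vapply(labs, function(l)
    sum(intervals$family == f & intervals$subgenome == l), numeric(1)),
    simplify = FALSE)
  truth <- structure(list(
    intervals = intervals,
    family_proportion = planted_bases / total_length,
    true_copies = true_copies,
    total_length = total_length,
    subgenome_lengths = nchar(res$seqs)
  ), class = "genome_truth")
  list(sequences = res$seqs, truth = truth, subgenomes = subgenomes)
}

#' Write genome and truth annotations to files
#'
#' Emits per-subgenome FASTA, a truth BED (chrom = subgenome label,
#' 0-based half-open) and a truth JSON with proportions and copy counts.
#'
#' @param genome result of \code{\link{assemble_genome}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, fa, width = 80L)
  bed <- file.path(dir, "truth.bed")
  iv <- genome$truth$intervals
  if (nrow(iv)) {
    gr <- GenomicRanges::GRanges(
      seqnames = iv$subgenome,
      ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
      strand = iv$strand, name = iv$family)
    rtracklayer::export.bed(gr, bed)
  } else {
    file.create(bed)
  }
  js <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    family_proportion = as.list(genome$truth$family_proportion),
    true_copies = lapply(genome$truth$true_copies, as.list),
    total_length = genome$truth$total_length
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, bed = bed, json = js))
}
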