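## Domain exemplar library --------------------------------------------------
##
## A small, fully synthetic stand-in for a reference domain database: one
## exemplar sequence per protein domain / rDNA component used both to
## realize planted repeat templates and to annotate cluster consensi.

EXEMPLAR_LENGTHS <- c(
  RT = 300L, RH = 240L, INT = 300L, TRANSPOSASE = 300L,
  rDNA_18S = 1811L, rDNA_5.8S = 168L, rDNA_26S = 3407L, rDNA_5S = 180L
)

#' Generate the synthetic domain exemplar library
#'
#' Deterministically generates one random exemplar sequence per domain id
#' (RT, RH, INT, TRANSPOSASE and the rDNA components). The same library
#' seeds the genome simulator's LTR/transposon/rDNA templates and the
#' annotation scanner, playing the role a curated domain database plays
#' for real reads.
#'
#' @param seed integer seed fixing the library content.
#' @param lengths named integer vector of exemplar lengths (bp), each
#'   at least 60.
#' @return data.frame with columns \code{domain_id}, \code{source},
#'   \code{sequence}; class \code{exemplar_library}.
#' @export
make_exemplar_library <- function(seed = 101L, lengths = EXEMPLAR_LENGTHS) {
  if (any(lengths < 60)) stop("exemplar length must be >= 60 bp")
  if (anyDuplicated(names(lengths))) stop("exemplar ids must be unique")
  with_seed(seed, {
    seqs <- vapply(lengths, function(n) random_dna(n, gc = 0.5), character(1))
  })
  structure(data.frame(domain_id = names(lengths),
                       source = "synthetic",
                       sequence = unname(seqs),
                       stringsAsFactors = FALSE),
            class = c("exemplar_library", "data.frame"))
}

#' Write / read an exemplar library as FASTA
#'
#' Headers are structured as \code{domain_id|source}.
#'
#' @param library an \code{exemplar_library}.
#' @param path FASTA file path.
#' @return \code{read_exemplar_library} returns an \code{exemplar_library}.
#' @export
write_exemplar_library <- function(library, path) {
  ss <- Biostrings::DNAStringSet(library$sequence)
  names(ss) <- paste(library$domain_id, library$source, sep = "|")
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' @rdname write_exemplar_library
#' @export
read_exemplar_library <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  structure(data.frame(domain_id = vapply(parts, `[`, "", 1),
                       source = vapply(parts, function(p) p[2] %||% NA_character_, ""),
                       sequence = as.character(ss),
                       stringsAsFactors = FALSE),
            class = c("exemplar_library", "data.frame"))
}

#' Default bundled exemplar library
#'
#' Reads the synthetic exemplar FASTA shipped with the package.
#' @return an \code{exemplar_library}.
#' @export
default_exemplar_library <- function() {
  p <- system.file("extdata", "domain_exemplars_synthetic.fasta",
                   package = "repeatscape")
  if (!nzchar(p)) return(make_exemplar_library())
  read_exemplar_library(p)
}

exemplar_seq <- function(library, id) {
  i <- match(id, library$domain_id)
  if (is.na(i)) stop("no exemplar for domain '", id, "' in library")
  library$sequence[i]
}

## Template realization -----------------------------------------------------

#' Realize repeat family templates from specifications
#'
#' Turns each \code{\link{repeat_family_spec}} into a concrete template
#' sequence, recording exact 0-based half-open coordinates of every
#' structural feature (LTRs, internal domains, TIRs, rDNA components).
#' rDNA templates are the concatenation of their components in the stated
#' order; components whose label matches a library exemplar of equal
#' length (e.g. 18S) reuse the exemplar sequence, the others (spacers)
#' are drawn at random.
#'
#' @param specs list of \code{repeat_family_spec}.
#' @param seed integer seed.
#' @param library an \code{exemplar_library}; defaults to the bundled one.
#' @return a \code{repeat_library}: list of realized templates, each with
#'   \code{name}, \code{kind}, \code{sequence}, \code{features}
#'   (data.frame label/start/end/strand) and the originating \code{spec}.
#' @export
build_repeat_library <- function(specs, seed = 1L,
                                 library = default_exemplar_library()) {
  if (inherits(specs, "repeat_family_spec")) specs <- list(specs)
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("family names must be unique")
  templates <- with_seed(seed, lapply(specs, realize_template, library = library))
  names(templates) <- nm
  structure(templates, class = "repeat_library")
}

realize_template <- function(spec, library) {
  feats <- data.frame(label = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  add_feat <- function(label, start, len, strand = "+") {
    feats <<- rbind(feats, data.frame(label = label, start = start,
                                      end = start + len, strand = strand,
                                      stringsAsFactors = FALSE))
  }
  seqc <- switch(spec$kind,
    satellite = ,
    simple = {
      s <- spec$monomer %||% random_dna(spec$monomer_length, gc = 0.5)
      add_feat("monomer", 0L, nchar(s))
      s
    },
    LTR_retro = {
      ltr <- random_dna(spec$ltr_length, gc = 0.5)
      pieces <- character(0)
      pos <- 0L
      push <- function(s, label = NULL, strand = "+") {
        pieces <<- c(pieces, s)
        if (!is.null(label)) add_feat(label, pos, nchar(s), strand)
        pos <<- pos + nchar(s)
      }
      push(ltr, "LTR")
      push(random_dna(spec$spacer_length, 0.5))
      for (d in spec$domain_order) {
        push(mutate_seq(exemplar_seq(library, d), spec$template_divergence), d)
        push(random_dna(spec$spacer_length, 0.5))
      }
      push(ltr, "LTR")
      paste(pieces, collapse = "")
    },
    DNA_transposon = {
      tir <- random_dna(spec$tir_length, gc = 0.5)
      sp <- spec$spacer_length
      s <- paste0(tir, random_dna(sp, 0.5),
                  mutate_seq(exemplar_seq(library, "TRANSPOSASE"),
                             spec$template_divergence),
                  random_dna(sp, 0.5), revcomp(tir))
      add_feat("TIR", 0L, nchar(tir))
      add_feat("TRANSPOSASE", nchar(tir) + sp,
               nchar(exemplar_seq(library, "TRANSPOSASE")))
      add_feat("TIR", nchar(s) - nchar(tir), nchar(tir), "-")
      s
    },
    rDNA = {
      comp <- spec$components
      if (is.null(comp) || is.null(names(comp)))
        stop("rDNA family '", spec$name, "' requires named component lengths")
      pieces <- character(length(comp))
      pos <- 0L
      for (i in seq_along(comp)) {
        id <- names(comp)[i]
        ex_id <- paste0("rDNA_", id)
        s <- if (ex_id %in% library$domain_id &&
                 nchar(exemplar_seq(library, ex_id)) == comp[i])
          mutate_seq(exemplar_seq(library, ex_id), spec$template_divergence)
        else random_dna(comp[i], gc = 0.5)
        add_feat(id, pos, comp[[i]])
        pieces[i] <- s
        pos <- pos + comp[[i]]
      }
      paste(pieces, collapse = "")
    })
  list(name = spec$name, kind = spec$kind, sequence = seqc,
       length = nchar(seqc), features = feats, spec = spec)
}

#' @export
print.repeat_library <- function(x, ...) {
  cat("Repeat library with", length(x), "realized templates:\n")
  for (t in x)
    cat(sprintf("  %-12s %-14s %6d bp, %d features\n",
                t$name, t$kind, t$length, nrow(t$features)))
  invisible(x)
}
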