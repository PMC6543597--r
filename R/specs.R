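#' Specify one repeat family to plant in a synthetic genome
#'
#' A parameterized template for a repeat family of one of five kinds:
#' \describe{
#'   \item{LTR_retro}{an LTR retroelement whose internal protein domains
#'     appear in a stated order (Gypsy-like RT-RH-INT or Copia-like
#'     INT-RT-RH), flanked by two identical long terminal repeats.}
#'   \item{satellite}{a tandem repeat with a monomer in roughly the
#'     40--360 bp range, planted as contiguous arrays by default.}
#'   \item{DNA_transposon}{a class II element: terminal inverted repeats
#'     around a transposase domain.}
#'   \item{rDNA}{a ribosomal RNA gene unit assembled by concatenating
#'     labelled components of fixed lengths (e.g. ETS-18S-ITS1-5.8S-ITS2-26S).}
#'   \item{simple}{an arbitrary template sequence planted as-is.}
#' }
#'
#' @param name family label.
#' @param kind one of \code{"LTR_retro"}, \code{"satellite"},
#'   \code{"DNA_transposon"}, \code{"rDNA"}, \code{"simple"}.
#' @param monomer monomer/template sequence (satellite, simple); or NULL to
#'   draw a random one of length \code{monomer_length}.
#' @param monomer_length length of the random monomer when \code{monomer}
#'   is NULL.
#' @param components named integer vector of component lengths (rDNA only),
#'   in unit order; components whose name matches a domain exemplar of the
#'   same length are realized with the exemplar sequence.
#' @param domain_order ordered character vector of internal domains
#'   (LTR_retro only), e.g. \code{c("RT","RH","INT")}.
#' @param copies named non-negative integer vector: copies per subgenome.
#' @param divergence per-copy substitution fraction in [0, 0.3].
#' @param template_divergence substitution fraction applied once to
#'   exemplar-derived template parts (retro/transposase domains, rDNA
#'   exemplar components) when the template is realized, so that
#'   different families sharing a domain stay well-separated at the DNA
#'   level (as real superfamilies are) while remaining detectable by the
#'   domain scanner.
#' @param array_mode \code{"tandem"} (contiguous array) or
#'   \code{"dispersed"}; tandem is the default for satellites and rDNA.
#' @param ltr_length,tir_length,spacer_length structural element lengths
#'   (bp) used when realizing LTR_retro / DNA_transposon templates.
#' @return an object of class \code{repeat_family_spec}.
#' @export
repeat_family_spec <- function(name, kind, monomer = NULL, monomer_length = 100L,
                               components = NULL, domain_order = NULL,
                               copies, divergence = 0,
                               template_divergence = 0.12,
                               array_mode = NULL,
                               ltr_length = 100L, tir_length = 15L,
                               spacer_length = 10L) {
  kinds <- c("LTR_retro", "satellite", "DNA_transposon", "rDNA", "simple")
  if (!kind %in% kinds)
    stop("unknown repeat kind '", kind, "'; must be one of ",
         paste(kinds, collapse = ", "))
  if (kind == "LTR_retro" && (is.null(domain_order) || !length(domain_order)))
    stop("LTR_retro family '", name, "' requires a non-empty domain_order")
  if (divergence < 0 || divergence > 0.3)
    stop("per-copy divergence must lie in [0, 0.3]")
  if (is.null(names(copies)) || any(!nzchar(names(copies))))
    stop("copies must be a named vector (subgenome label -> count)")
  if (any(copies < 0)) stop("copies must be non-negative")
  if (!is.null(monomer) && nchar(monomer) < 10)
    stop("monomer length must be >= 10")
  if (is.null(monomer) && kind %in% c("satellite", "simple") && monomer_length < 10)
    stop("monomer length must be >= 10")
  if (is.null(array_mode))
    array_mode <- if (kind %in% c("satellite", "rDNA")) "tandem" else "dispersed"
  structure(list(
    name = name, kind = kind, monomer = monomer,
    monomer_length = as.integer(monomer_length),
    components = components, domain_order = domain_order,
    copies = copies, divergence = divergence,
    template_divergence = template_divergence, array_mode = array_mode,
    ltr_length = as.integer(ltr_length), tir_length = as.integer(tir_length),
    spacer_length = as.integer(spacer_length),
    inert = all(copies == 0)
  ), class = "repeat_family_spec")
}

#' Specify one subgenome of a synthetic polyploid
#'
#' @param label subgenome label (e.g. "A", "C", "D").
#' @param background_length bp of random non-repetitive background; at
#'   least 10 kb so that read simulation is meaningful.
#' @param gc background GC fraction; the default reflects the ~43\% GC
#'   typical of oat whole-genome reads.
#' @return an object of class \code{subgenome_spec}.
#' @export
subgenome_spec <- function(label, background_length, gc = 0.4323) {
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  if (background_length < 10000)
    stop("background_length must be >= 10 kb")
  structure(list(label = label,
                 background_length = as.integer(background_length),
                 gc = gc),
            class = "subgenome_spec")
}

#' Specify the paired-end sequencing design for read simulation
#'
#' Defaults emulate a 2 x 250 bp library from 500 bp inserts with a
#' substitution-only error model.
#'
#' @param read_length read length in bp.
#' @param insert_length insert (fragment) length in bp; must be at least
#'   \code{read_length}.
#' @param coverage fold coverage of the genome.
#' @param error_rate per-base substitution error rate, in [0, 0.05].
#' @return an object of class \code{read_sim_spec}.
#' @export
read_sim_spec <- function(read_length = 250L, insert_length = 500L,
                          coverage = 5, error_rate = 0.005) {
  if (insert_length < read_length)
    stop("insert_length must be >= read_length")
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]")
  structure(list(read_length = as.integer(read_length),
                 insert_length = as.integer(insert_length),
                 coverage = coverage, error_rate = error_rate),
            class = "read_sim_spec")
}
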