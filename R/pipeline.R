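#' Validate a pipeline configuration
#'
#' A single list drives the whole pipeline; unknown keys are rejected
#' and a seed is mandatory whenever simulation is requested. All
#' randomness flows from the one root seed via per-stage derived seeds.
#'
#' @param config named list with blocks: \code{seed} (required for
#'   simulation), \code{subgenomes} (list of \code{subgenome_spec}),
#'   \code{families} (list of \code{repeat_family_spec}),
#'   \code{read_sim} (a \code{read_sim_spec}), \code{stated_1C} (named
#'   numeric per subgenome; required when specificity is enabled),
#'   optional parameter blocks \code{kmer} (k, thresholds),
#'   \code{cluster} (min_overlap_frac, min_identity),
#'   \code{annotate} (min_prop), \code{specificity}
#'   (alpha, floor, enabled).
#' @return the validated config (with defaults filled), class
#'   \code{pipeline_config}.
#' @export
pipeline_config <- function(config) {
  known <- c("seed", "subgenomes", "families", "read_sim", "stated_1C",
             "kmer", "cluster", "annotate", "specificity")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  simulating <- !is.null(config$subgenomes)
  if (simulating && is.null(config$seed))
    stop("seed is mandatory when simulation is requested")
  config$read_sim <- config$read_sim %||% read_sim_spec()
  config$kmer <- utils::modifyList(
    list(k = 16L, thresholds = c(2, 5, 10, 100)), config$kmer %||% list())
  config$cluster <- utils::modifyList(
    list(min_overlap_frac = 0.5, min_identity = 0.9),
    config$cluster %||% list())
  config$annotate <- utils::modifyList(
    list(min_prop = 0.005), config$annotate %||% list())
  config$specificity <- utils::modifyList(
    list(enabled = TRUE, alpha = 0.2, floor = 10, max_neighbours = Inf),
    config$specificity %||% list())
  if (isTRUE(config$specificity$enabled) && simulating &&
      is.null(config$stated_1C))
    stop("stated_1C genome sizes are required when specificity is enabled")
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full repeat-landscape pipeline
#'
#' Stages, in order: simulate (genome + per-subgenome read samples),
#' k-mer repetitivity, read clustering, cluster annotation (consensus,
#' domain scan, shape), tandem periodicity, and per-subgenome copy
#' number / genome specificity. Identical config and seed give an
#' identical report.
#'
#' @param config a \code{pipeline_config} (or plain list, validated
#'   here).
#' @param out_dir optional output directory for tables and a
#'   MANIFEST.json.
#' @param quiet suppress stage messages.
#' @return a \code{run_report}: list with \code{truth},
#'   \code{read_stats}, \code{curves}, \code{cluster_table},
#'   \code{annotation}, \code{composition}, \code{monomers},
#'   \code{copy_number}, \code{specificity}, \code{provenance}.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- simulate ---
  sim <- stage("simulate", {
    say("[simulate] building repeat library and genome")
    lib <- build_repeat_library(config$families,
                                seed = derive_seed(config$seed, "library"))
    genome <- assemble_genome(config$subgenomes, lib,
                              seed = derive_seed(config$seed, "genome"))
    samples <- list()
    for (sg in names(genome$sequences)) {
      s1c <- if (!is.null(config$stated_1C)) config$stated_1C[[sg]] else NULL
      samples[[sg]] <- simulate_reads(
        genome$sequences[sg], config$read_sim,
        seed = derive_seed(config$seed, paste0("reads_", sg)),
        stated_1C = s1c)
    }
    pooled <- unlist(lapply(samples, `[[`, "reads"))
    names(pooled) <- sub("^[^.]*\\.", "", names(pooled))
    list(lib = lib, genome = genome, samples = samples, pooled = pooled)
  })
  say("[simulate] %d reads pooled over %d subgenomes",
      length(sim$pooled), length(sim$samples))

  ## --- kmer ---
  total_1C <- if (!is.null(config$stated_1C)) sum(unlist(config$stated_1C))
              else sim$genome$truth$total_length
  curves <- stage("kmer", {
    spec <- count_kmers(sim$pooled, k = config$kmer$k,
                        genome_equivalents =
                          sum(nchar(sim$pooled)) / total_1C)
    repetitivity_curve(spec, config$kmer$thresholds)
  })
  say("[kmer] k=%d curve computed", config$kmer$k)

  ## --- cluster ---
  clustering <- stage("cluster", {
    edges <- find_overlaps(sim$pooled,
                           min_overlap_frac = config$cluster$min_overlap_frac,
                           min_identity = config$cluster$min_identity)
    cluster_reads(edges)
  })
  ctab <- make_cluster_table(clustering)
  nb <- cluster_neighbours(clustering)
  say("[cluster] %d clusters over %d reads (%d singletons)",
      length(clustering$clusters), clustering$n_reads,
      length(clustering$singletons))

  ## --- annotate + tandem ---
  ann <- stage("annotate", {
    lib_ex <- default_exemplar_library()
    big <- ctab$cluster_id[ctab$proportion >= config$annotate$min_prop]
    consensi <- list(); calls <- list(); shapes <- list(); monos <- list()
    gc_per <- numeric()
    for (cid in big) {
      members <- clustering$clusters[[cid]]
      reads <- sim$pooled[members]
      cons <- build_consensus(reads)
      consensi[[as.character(cid)]] <- cons
      per <- detect_periodicity(cons)
      monos[[as.character(cid)]] <- per
      hits <- scan_domains(cons, lib_ex)
      calls[[as.character(cid)]] <- classify_superfamily(hits, per)
      shapes[[as.character(cid)]] <-
        classify_shape(cluster_subgraph(clustering, cid))
      gc_per[as.character(cid)] <- gc_content(reads)
    }
    list(consensi = consensi, calls = calls, shapes = shapes,
         monomers = monos, gc = gc_per, annotated = big)
  })
  call_df <- data.frame(
    cluster_id = ctab$cluster_id,
    category = vapply(as.character(ctab$cluster_id), function(k)
      if (!is.null(ann$calls[[k]])) ann$calls[[k]]$category
      else "unclassified", character(1)),
    shape = vapply(as.character(ctab$cluster_id), function(k)
      if (!is.null(ann$shapes[[k]])) ann$shapes[[k]]$shape
      else NA_character_, character(1)),
    stringsAsFactors = FALSE)
  composition <- summarize_composition(ctab, call_df, ann$gc)
  tandem_ids <- names(ann$monomers)[vapply(ann$monomers, function(m)
    m$classification != "none", logical(1))]
  monomers <- monomer_table(ann$monomers[tandem_ids])
  say("[annotate] %d clusters annotated, %d with tandem periodicity",
      length(ann$annotated), nrow(monomers))

  ## --- specificity ---
  speci <- NULL; copy_tab <- NULL
  if (isTRUE(config$specificity$enabled)) {
    res <- stage("specificity", {
      probes <- select_probes(ctab, nb, ann$consensi,
                              max_neighbours = config$specificity$max_neighbours)
      rows <- list(); calls <- list()
      for (i in seq_len(nrow(probes))) {
        frag <- probes$sequence[i]
        cp <- numeric()
        for (sg in names(sim$samples)) {
          rs <- sim$samples[[sg]]
          mr <- map_reads(rs, frag)
          cp[sg] <- copies_per_1C(as.integer(mr), rs$read_length,
                                  nchar(frag), rs$genome_equivalents)
          rows[[length(rows) + 1L]] <- data.frame(
            fragment = sprintf("CL%d_probe", probes$cluster_id[i]),
            sample = sg, mapped_reads = as.integer(mr),
            copies_per_1C = cp[sg],
            proportion = cp[sg] * nchar(frag) / rs$stated_1C,
            stringsAsFactors = FALSE)
        }
        if (length(cp) >= 2)
          calls[[sprintf("CL%d_probe", probes$cluster_id[i])]] <-
            classify_specificity(cp, alpha = config$specificity$alpha,
                                 floor = config$specificity$floor)
      }
      list(copy_tab = if (length(rows)) do.call(rbind, rows) else NULL,
           calls = calls, probes = probes)
    })
    copy_tab <- res$copy_tab
    speci <- res
    say("[specificity] %d probe fragments quantified across %d samples",
        nrow(res$probes), length(sim$samples))
  }

  cfg_json <- jsonlite::toJSON(list(seed = config$seed,
                                    kmer = config$kmer,
                                    cluster = config$cluster,
                                    annotate = config$annotate),
                               auto_unbox = TRUE)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  report <- structure(list(
    truth = sim$genome$truth,
    read_stats = lapply(sim$samples, function(s)
      list(n_reads = length(s$reads), genome_equivalents = s$genome_equivalents)),
    curves = curves,
    clustering = clustering,
    cluster_table = ctab,
    neighbours = nb,
    annotation = ann,
    calls = call_df,
    composition = composition,
    monomers = monomers,
    copy_number = copy_tab,
    specificity = if (!is.null(speci)) speci$calls else NULL,
    probes = if (!is.null(speci)) speci$probes else NULL,
    provenance = list(seed = config$seed,
                      config_hash = unname(tools::md5sum(tf)),
                      package_version =
                        as.character(utils::packageVersion("repeatscape")),
                      elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs")))
  ), class = "run_report")
  unlink(tf)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a run report's tables to a directory
#'
#' @param report a \code{run_report}.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(
    wtsv(report$cluster_table, "cluster_table.tsv"),
    wtsv(report$curves, "repetitivity_curve.tsv"),
    wtsv(report$calls, "cluster_annotation.tsv"),
    wtsv(report$monomers, "monomer_table.tsv"))
  if (!is.null(report$copy_number))
    files <- c(files, wtsv(report$copy_number, "copy_number.tsv"))
  if (!is.null(report$specificity)) {
    sp <- data.frame(
      fragment = names(report$specificity),
      category = vapply(report$specificity, `[[`, "", "category"),
      warning_flag = vapply(report$specificity, `[[`, NA, "warning_flag"),
      stringsAsFactors = FALSE)
    files <- c(files, wtsv(sp, "specificity.tsv"))
  }
  mf <- file.path(dir, "MANIFEST.json")
  jsonlite::write_json(list(files = basename(files),
                            provenance = report$provenance),
                       mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  reads: %d in %d clusters (+%d singletons)\n",
              x$clustering$n_reads, length(x$clustering$clusters),
              length(x$clustering$singletons)))
  cat(sprintf("  clustered fraction: %.1f%%\n", x$composition$clustered_percent))
  cat(sprintf("  tandem clusters: %d; probes: %s\n", nrow(x$monomers),
              if (is.null(x$probes)) "-" else nrow(x$probes)))
  invisible(x)
}

#' Study-scale hexaploid demonstration configuration
#'
#' The package's reference synthetic conditions: an A/C/D hexaploid with
#' 100 kb of background per subgenome at 43\% GC, carrying one repeat
#' family per genome-specificity category plus a Copia family --
#' satellites with 43 bp (C-specific, 400 copies), 150 bp (A-specific,
#' 100 copies), 340 bp (D-specific, 40 copies) and 360 bp (A+D, 25+25
#' copies) monomers, a Gypsy element (RT-RH-INT) at 15 copies per
#' subgenome and a Copia element (INT-RT-RH) at 12 copies per subgenome
#' (Gypsy:Copia base ratio 2.5:1) -- sequenced at 5x with 2 x 250 bp
#' pairs and 0.5\% substitution error.
#'
#' @param seed root seed.
#' @param coverage fold coverage (default 5).
#' @return a \code{pipeline_config}.
#' @export
hexaploid_demo_config <- function(seed, coverage = 5) {
  subg <- list(subgenome_spec("A", 100000L),
               subgenome_spec("C", 100000L),
               subgenome_spec("D", 100000L))
  fams <- list(
    repeat_family_spec("satC43", "satellite", monomer_length = 43L,
                       copies = c(A = 0L, C = 400L, D = 0L), divergence = 0.02),
    repeat_family_spec("satA150", "satellite", monomer_length = 150L,
                       copies = c(A = 100L, C = 0L, D = 0L), divergence = 0.02),
    repeat_family_spec("satD340", "satellite", monomer_length = 340L,
                       copies = c(A = 0L, C = 0L, D = 40L), divergence = 0.02),
    repeat_family_spec("satAD360", "satellite", monomer_length = 360L,
                       copies = c(A = 25L, C = 0L, D = 25L), divergence = 0.02),
    # element lengths: 2*ltr + 4*spacer + RT+RH+INT = 2*110+40+840 = 1100 bp
    # (gypsy) and 2*60+40+840 = 1000 bp (copia); 25 and 11 copies per
    # subgenome give a genome-wide Gypsy:Copia base ratio of exactly 2.5.
    # TRIM-like short LTRs (below the minimum qualifying overlap) keep
    # left/right-LTR reads from circularizing the consensus layout.
    repeat_family_spec("gypsy1", "LTR_retro",
                       domain_order = c("RT", "RH", "INT"),
                       copies = c(A = 25L, C = 25L, D = 25L),
                       divergence = 0.02, ltr_length = 110L),
    repeat_family_spec("copia1", "LTR_retro",
                       domain_order = c("INT", "RT", "RH"),
                       copies = c(A = 11L, C = 11L, D = 11L),
                       divergence = 0.02, ltr_length = 60L))
  pipeline_config(list(
    seed = seed,
    subgenomes = subg,
    families = fams,
    read_sim = read_sim_spec(coverage = coverage),
    # detection floor 5 copies/1C suits this demonstration's copy-number
    # scale (smallest planted family: 11 copies; background maps at 1-2)
    specificity = list(floor = 5),
    stated_1C = list(A = 100000 + 150 * 100 + 360 * 25 + 25 * 1100 + 11 * 1000,
                     C = 100000 + 43 * 400 + 25 * 1100 + 11 * 1000,
                     D = 100000 + 340 * 40 + 360 * 25 + 25 * 1100 + 11 * 1000)))
}
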