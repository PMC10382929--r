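# End-to-end orchestration: karyotype comparison -> event inference ->
# hotspot tally -> sequence evidence on a synthetic genome -> read
# simulation -> toy assembly, with TSV/JSON reports per stage and a
# consolidated JSON summary.  All randomness is seeded from the config,
# so a report bundle is reproducible byte for byte.

#' Build a pipeline run configuration
#'
#' Every parameter defaults to the study-protocol value where one
#' exists: minimum overlap 200 bp at 99% identity, 300 bp paired-end
#' reads with 530 bp inserts, and read filters removing pairs with more
#' than 10% N or more than 50% of bases at Q <= 20.
#'
#' @param out_dir Output directory for the report bundle.
#' @param stages Stages to run, a subset of `compare`, `infer`,
#'   `hotspots`, `stretches`, `motifs`, `simulate`, `assemble`.
#' @param ancestral,mrca Fixture name (or grammar file path) of the
#'   deep ancestral karyotype and of the intermediate ancestor used for
#'   the species branches.
#' @param derived Two fixture names (or file paths) for the derived
#'   species karyotypes.
#' @param seed Integer master seed.
#' @param min_overlap,min_identity Assembly overlap parameters
#'   (defaults 200 bp, 0.99).
#' @param read_len,insert_len,coverage Read-simulation parameters
#'   (defaults 300 bp, 530 bp, 30x).
#' @param error_rate Read substitution error rate.
#' @param max_n_frac,q_thresh,max_lowq_frac Read-filter parameters
#'   (defaults 0.10, 20, 0.50).
#' @param min_motif_len Minimum conserved-motif length.
#' @param toy_scale Use the five-fold shrunken toy genome for the
#'   simulate/assemble stages so they run in seconds; read and overlap
#'   parameters left at their defaults are shrunk along with it
#'   (150 bp reads, 300 bp inserts, 60 bp overlaps).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("compare", "infer", "hotspots",
                                       "stretches", "motifs", "simulate",
                                       "assemble"),
                            ancestral = "MRCA_Anoplura",
                            mrca = "MRCA_Linognathus",
                            derived = c("L_vituli", "L_africanus"),
                            seed = 1L,
                            min_overlap = 200L, min_identity = 0.99,
                            read_len = 300L, insert_len = 530L,
                            coverage = 30, error_rate = 0,
                            max_n_frac = 0.10, q_thresh = 20L,
                            max_lowq_frac = 0.50,
                            min_motif_len = 20L, toy_scale = TRUE) {
  if (toy_scale) {
    # toy circles are a few hundred bp; shrink protocol-scale read and
    # overlap defaults with them unless explicitly overridden
    if (missing(read_len)) read_len <- 150L
    if (missing(insert_len)) insert_len <- 300L
    if (missing(min_overlap)) min_overlap <- 60L
  }
  structure(list(
    out_dir = out_dir, stages = stages, ancestral = ancestral,
    mrca = mrca, derived = derived, seed = as.integer(seed),
    min_overlap = as.integer(min_overlap), min_identity = min_identity,
    read_len = as.integer(read_len), insert_len = as.integer(insert_len),
    coverage = coverage, error_rate = error_rate,
    max_n_frac = max_n_frac, q_thresh = as.integer(q_thresh),
    max_lowq_frac = max_lowq_frac,
    min_motif_len = as.integer(min_motif_len), toy_scale = toy_scale
  ), class = "run_config")
}

#' Read a flat key/value config file
#'
#' One `key: value` pair per line (a flat YAML-style document); `#`
#' comments and blank lines are ignored.  Values are coerced to
#' numeric/logical where possible; `stages` and `derived` may be
#' comma-separated.  Keys mirror [pipeline_config()] arguments.
#'
#' @param path Config file path.
#' @param out_dir Output directory (overrides any `out_dir` in the
#'   file when non-`NULL`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  args <- list()
  for (p in kv) {
    key <- trimws(p[1L])
    val <- trimws(paste(p[-1L], collapse = ":"))
    if (key %in% c("stages", "derived")) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    } else if (val %in% c("TRUE", "FALSE", "true", "false")) {
      val <- as.logical(toupper(val))
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      val <- as.numeric(val)
    }
    args[[key]] <- val
  }
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (is.null(args$out_dir)) stop("config gives no out_dir")
  do.call(pipeline_config, args)
}

.resolve_karyotype <- function(x) {
  if (inherits(x, "karyotype")) return(x)
  if (x %in% names(.FIXTURE_SPECIES)) return(load_fixture(x))
  if (file.exists(x)) return(read_karyotype(x, species = basename(x)))
  stop("cannot resolve karyotype '", x, "' (not a fixture name or file)")
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages and writes one report file per stage
#' into `config$out_dir`, plus a consolidated `summary.json`:
#' karyotype summaries, shared-minichromosome count, inferred event
#' lists per branch, minimum recombination event bounds per hotspot
#' anchor, the hotspot ranking, conserved-motif and shared-stretch
#' tables on a synthetic genome, and a toy re-assembly of simulated
#' reads.  Reports are byte-identical across runs with the same config.
#'
#' @param config A `run_config` from [pipeline_config()] or
#'   [read_run_config()].
#' @return The report bundle (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  bundle <- list()
  log_msg <- function(...) {
    message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  }

  anc <- NULL; mrca <- NULL; der <- NULL
  need_karyotypes <- any(c("compare", "infer", "hotspots") %in%
                           config$stages)
  if (need_karyotypes) {
    anc <- .resolve_karyotype(config$ancestral)
    mrca <- .resolve_karyotype(config$mrca)
    der <- lapply(config$derived, .resolve_karyotype)
  }

  if ("compare" %in% config$stages) {
    .stage("compare", {
      log_msg("compare: %s vs %s", der[[1L]]$species, der[[2L]]$species)
      summaries <- lapply(c(list(anc, mrca), der), summarize_karyotype)
      sm <- do.call(rbind, lapply(summaries, function(s) {
        as.data.frame(unclass(s), stringsAsFactors = FALSE)
      }))
      utils::write.table(sm, out("karyotype_summaries.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      rep <- compare_karyotypes(der[[1L]], der[[2L]])
      write_comparison_tsv(rep, out("comparison.tsv"))
      bundle$summaries <- summaries
      bundle$comparison <- rep
    })
  }

  if ("infer" %in% config$stages) {
    .stage("infer", {
      log_msg("infer: events on three branches")
      branches <- c(
        stats::setNames(list(infer_events(anc, mrca)),
                        paste0(config$ancestral, "->", config$mrca)),
        stats::setNames(
          lapply(der, function(d) infer_events(mrca, d)),
          paste0(config$mrca, "->", config$derived))
      )
      for (nm in names(branches)) {
        events_to_json(branches[[nm]],
                       out(paste0("events_", gsub("[^A-Za-z0-9_.-]", "_",
                                                  nm), ".json")))
      }
      bundle$branches <- branches
    })
  }

  if ("hotspots" %in% config$stages) {
    .stage("hotspots", {
      if (is.null(bundle$branches)) stop("requires the infer stage")
      tally <- hotspot_tally(bundle$branches)
      write_hotspot_tsv(tally, out("hotspots.tsv"))
      species_events <- do.call(rbind, bundle$branches[-1L])
      bounds <- lapply(utils::head(tally$anchor, 3L), function(a) {
        b <- min_recombination_events(species_events, a, mrca)
        list(anchor = a, min_events = as.integer(b),
             max_events = attr(b, "max_events"),
             ambiguous = attr(b, "ambiguous"))
      })
      bundle$hotspots <- tally
      bundle$min_event_bounds <- bounds
    })
  }

  genome <- NULL; derived_genome <- NULL; truth <- NULL
  if (any(c("stretches", "motifs", "simulate", "assemble") %in%
            config$stages)) {
    scale <- if (config$toy_scale) "toy" else "full"
    ncr_range <- if (config$toy_scale) c(250L, 400L) else c(686L, 1296L)
    motifs <- if (config$toy_scale) {
      default_motif_spec(at_len = 30L, gc_len = 30L)
    } else default_motif_spec()
    genome <- generate_ancestral_genome(
      gene_lengths = default_gene_lengths(scale), ncr_len = ncr_range,
      motif_spec = motifs, seed = config$seed)
  }

  if ("simulate" %in% config$stages) {
    .stage("simulate", {
      log_msg("simulate: events + paired-end reads")
      ae <- apply_events(genome, n_events = 2L,
                         types = c("duplication_insert",
                                   "partial_duplication"),
                         seed = config$seed + 1L)
      derived_genome <- ae$genome
      truth <- ae$truth
      write_genome_fasta(derived_genome, out("synthetic_genome.fasta"))
      writeLines(jsonlite::toJSON(truth$events, dataframe = "rows",
                                  auto_unbox = TRUE, na = "null",
                                  digits = NA),
                 out("truth_events.json"))
      reads <- simulate_reads(derived_genome, coverage = config$coverage,
                              read_len = config$read_len,
                              insert_len = config$insert_len,
                              error_rate = config$error_rate,
                              seed = config$seed + 2L)
      write_fastq(reads, out("reads_1.fastq"), out("reads_2.fastq"))
      bundle$truth <- truth
      bundle$reads <- reads
      bundle$derived_genome <- derived_genome
    })
  }

  if ("stretches" %in% config$stages) {
    .stage("stretches", {
      g <- if (!is.null(bundle$derived_genome)) bundle$derived_genome else
        genome
      # the six longest genes, one sequence per name
      all_genes <- do.call(rbind, lapply(g$karyotype$minichromosomes,
                                         function(m) m$genes))
      all_genes <- all_genes[all_genes$status == "full" &
                               !is.na(all_genes$sequence), , drop = FALSE]
      all_genes <- all_genes[!duplicated(all_genes$name), , drop = FALSE]
      all_genes <- all_genes[order(-all_genes$length_bp, all_genes$name), ,
                             drop = FALSE]
      seqs <- stats::setNames(utils::head(all_genes$sequence, 6L),
                              utils::head(all_genes$name, 6L))
      tab <- stretch_table(seqs, include_revcomp = TRUE)
      utils::write.table(tab, out("stretches.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      bundle$stretches <- tab
    })
  }

  if ("motifs" %in% config$stages) {
    .stage("motifs", {
      g <- if (!is.null(bundle$derived_genome)) bundle$derived_genome else
        genome
      ncrs <- vapply(g$karyotype$minichromosomes, `[[`, character(1L),
                     "ncr_sequence")
      hits <- find_conserved_motifs(ncrs, min_len = config$min_motif_len)
      flat <- hits
      flat$offsets <- vapply(hits$offsets, paste, character(1L),
                             collapse = ",")
      utils::write.table(as.data.frame(flat), out("motifs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      bundle$motifs <- hits
    })
  }

  if ("assemble" %in% config$stages) {
    .stage("assemble", {
      if (is.null(bundle$reads)) stop("requires the simulate stage")
      log_msg("assemble: filter + two seed assemblies + NCR bait")
      g <- bundle$derived_genome
      reads <- filter_reads(bundle$reads,
                            max_n_frac = config$max_n_frac,
                            q_thresh = config$q_thresh,
                            max_lowq_frac = config$max_lowq_frac)
      # the two largest genes on different minichromosomes as seeds
      # (the cox1 / rrnS analogues of the emulated protocol)
      ix <- gene_index(g$karyotype)
      cand <- ix[ix$status == "full", ]
      lens <- vapply(seq_len(nrow(cand)), function(i) {
        m <- g$karyotype$minichromosomes[[cand$chrom[i]]]
        m$genes$length_bp[cand$position[i]]
      }, integer(1L))
      cand <- cand[order(-lens), ]
      seed1 <- cand[1L, ]
      seed2 <- cand[cand$chrom != seed1$chrom, ][1L, ]
      get_seq <- function(row) {
        m <- g$karyotype$minichromosomes[[row$chrom]]
        m$genes$sequence[row$position]
      }
      ctg1 <- iterative_extend(reads, get_seq(seed1),
                               min_overlap = config$min_overlap,
                               min_identity = config$min_identity)
      ctg2 <- iterative_extend(reads, get_seq(seed2),
                               min_overlap = config$min_overlap,
                               min_identity = config$min_identity)
      cons <- derive_ncr_consensus(ctg1, ctg2,
                                   min_overlap = config$min_overlap,
                                   min_identity = config$min_identity)
      contigs <- bait_assemble(reads, cons,
                               min_overlap = config$min_overlap,
                               min_identity = config$min_identity)
      write_contigs(contigs, out("contigs.fasta"),
                    report_path = out("assembly_report.json"),
                    ncr_consensus = as.character(cons))
      bundle$contigs <- contigs
      bundle$ncr_consensus <- as.character(cons)
    })
  }

  # consolidated summary
  summary <- list(seed = config$seed, stages = config$stages)
  if (!is.null(bundle$summaries)) {
    summary$karyotypes <- lapply(bundle$summaries, unclass)
  }
  if (!is.null(bundle$comparison)) {
    summary$shared_minichromosomes <- nrow(bundle$comparison$shared)
    summary$differing_minichromosomes <- nrow(bundle$comparison$differing)
  }
  if (!is.null(bundle$branches)) {
    summary$n_events_per_branch <- lapply(bundle$branches, nrow)
  }
  if (!is.null(bundle$min_event_bounds)) {
    summary$min_event_bounds <- bundle$min_event_bounds
  }
  if (!is.null(bundle$hotspots)) {
    summary$top_anchors <- utils::head(bundle$hotspots$anchor, 2L)
  }
  if (!is.null(bundle$contigs)) {
    summary$assembled_minichromosomes <-
      attr(bundle$contigs, "n_minichromosomes")
    summary$true_minichromosomes <-
      length(bundle$derived_genome$karyotype$minichromosomes)
  }
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, na = "null",
                              digits = NA, pretty = TRUE),
             out("summary.json"))
  bundle$summary <- summary
  invisible(bundle)
}
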