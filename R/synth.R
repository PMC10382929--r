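# Synthetic fragmented-genome generator: an ancestral minichromosomal
# genome with planted NCR motifs, a recombination-event applicator with
# a replayable ground-truth log, and a paired-end read simulator.  This
# is the test substrate for every other module: events applied here must
# be recoverable by infer_events(), planted motifs by
# find_conserved_motifs(), and simulated reads re-assemblable by the toy
# assembler.

#' Typical mitochondrial gene lengths
#'
#' Realistic per-gene lengths (bp) for the 37-gene vocabulary, used by
#' the generator: protein-coding genes at typical insect mitochondrial
#' sizes, rRNAs at 700/1200 bp, tRNAs at 65 bp.  The `"toy"` scale
#' shrinks everything about five-fold so that desk-scale assemblies run
#' in seconds.
#'
#' @param scale `"full"` or `"toy"`.
#' @return A named integer vector over the 37 canonical gene names.
#' @export
default_gene_lengths <- function(scale = c("full", "toy")) {
  scale <- match.arg(scale)
  pcg <- c(atp6 = 672L, atp8 = 159L, cox1 = 1530L, cox2 = 678L,
           cox3 = 784L, cytb = 1131L, nad1 = 939L, nad2 = 1000L,
           nad3 = 351L, nad4 = 1330L, nad4L = 288L, nad5 = 1717L,
           nad6 = 522L)
  rrna <- c(rrnS = 700L, rrnL = 1200L)
  trna <- structure(rep(65L, length(.TRNA_NAMES)), names = .TRNA_NAMES)
  full <- c(pcg, trna, rrna)
  if (scale == "toy") {
    full <- structure(pmax(30L, as.integer(round(full / 5))),
                      names = names(full))
  }
  full[c(.PCG_NAMES, .TRNA_NAMES, .RRNA_NAMES)]
}

#' Default gene-to-minichromosome partition
#'
#' The ten-minichromosome partition of the 37-gene vocabulary mirroring
#' the cattle-louse gene clusters (duplicate and pseudo copies removed),
#' including the single reverse-oriented `~Q-~nad1-~T` run.
#'
#' @return A character vector of gene-cluster strings in the karyotype
#'   grammar.
#' @export
default_gene_partition <- function() {
  c("E-cytb-S1-S2-R-nad4L-P-atp8",
    "rrnS-C-atp6-N",
    "I-cox1",
    "Y-cox2-nad6",
    "cox3-W-A",
    "~Q-~nad1-~T-G-nad3",
    "D-nad2",
    "K-nad4",
    "H-nad5-F-L2",
    "M-L1-rrnL-V")
}

#' Random gene-to-minichromosome partition
#'
#' Partitions the 37-gene vocabulary into `n` clusters of 2 to
#' `max_genes` genes uniformly at random (caller seeds the RNG, e.g.
#' via `seed`).
#'
#' @param n Number of minichromosomes.
#' @param max_genes Maximum genes per cluster (default 8, mirroring the
#'   observed 2-8 range).
#' @param seed Optional integer seed.
#' @return A character vector of `n` cluster strings.
#' @export
random_gene_partition <- function(n = 10L, max_genes = 8L, seed = NULL) {
  stopifnot(n >= 2L, 2L * n <= 37L, n * max_genes >= 37L)
  draw <- function() {
    genes <- sample(canonical_vocabulary()$name)
    repeat {
      sizes <- rep(2L, n)
      extra <- 37L - 2L * n
      if (extra > 0L) {
        add <- table(factor(sample(seq_len(n), extra, replace = TRUE),
                            levels = seq_len(n)))
        sizes <- sizes + as.integer(add)
      }
      if (max(sizes) <= max_genes) break
    }
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    vapply(seq_len(n), function(i) {
      paste(genes[starts[i]:ends[i]], collapse = "-")
    }, character(1L))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Default planted NCR motif specification
#'
#' Mirrors the conserved motifs observed in the large NCRs of sucking
#' lice: an AT-rich motif (45 bp, 100% A+T) upstream of the gene
#' cluster and a GC-rich motif (78 bp, 60% G+C) downstream of it.
#'
#' @param at_len,at_frac Length and A+T fraction of the upstream motif.
#' @param gc_len,gc_frac Length and G+C fraction of the downstream
#'   motif.
#' @return A list with elements `at` and `gc`.
#' @export
default_motif_spec <- function(at_len = 45L, at_frac = 1.0,
                               gc_len = 78L, gc_frac = 0.60) {
  list(at = list(len = as.integer(at_len), at_frac = at_frac),
       gc = list(len = as.integer(gc_len), gc_frac = gc_frac))
}

.motif_seq <- function(len, gc_frac) {
  random_seq(len, gc = gc_frac)
}

#' Generate a synthetic ancestral minichromosomal genome
#'
#' Builds a fragmented mitochondrial genome: each minichromosome is a
#' circle of one gene cluster plus one large NCR.  Gene sequences are
#' iid at the configured GC content; the NCR (identical across the
#' genome's minichromosomes, the toy limit of the observed high NCR
#' conservation) carries a planted AT-rich motif near its upstream end
#' and a planted GC-rich motif near its downstream end.  Fully
#' deterministic under `seed`.
#'
#' @param n_minichromosomes Number of minichromosomes (observed species
#'   range is 9-20; values outside it draw a warning).
#' @param partition Gene-cluster strings covering the 37-gene vocabulary
#'   exactly once (e.g. [default_gene_partition()] or
#'   [random_gene_partition()]); `NULL` draws a random partition.
#' @param ncr_len Length-2 numeric range for the NCR length (bp); one
#'   length is drawn per genome.
#' @param motif_spec See [default_motif_spec()].
#' @param gc Background GC fraction of gene and NCR sequence.
#' @param ncr_divergence Per-base substitution rate applied to the
#'   *background* (non-motif) positions of each minichromosome's copy
#'   of the NCR.  The default 0 makes NCRs identical across the genome
#'   (the toy limit of the observed high conservation, and the regime
#'   in which the toy assembler reconstructs circles exactly); a value
#'   around 0.1 yields NCRs that share only the planted motifs exactly,
#'   the regime for motif-discovery closed loops.
#' @param gene_lengths Named lengths per gene, see
#'   [default_gene_lengths()].
#' @param seed Integer seed.
#' @param attach_sequences Set `FALSE` for a fast karyotype-only genome
#'   (no sequences), sufficient for event-inference simulations.
#' @return An object of class `synthetic_genome`: a list with the
#'   `karyotype` (sequences attached per gene and per NCR), the shared
#'   `ncr_sequence`, the planted `motifs` (data frame), and the
#'   generating `seed` and parameters.
#' @export
generate_ancestral_genome <- function(n_minichromosomes = 10L,
                                      partition = default_gene_partition(),
                                      ncr_len = c(686L, 1296L),
                                      motif_spec = default_motif_spec(),
                                      gc = 0.30,
                                      ncr_divergence = 0,
                                      gene_lengths = default_gene_lengths(),
                                      seed = 42L,
                                      attach_sequences = TRUE) {
  if (n_minichromosomes < 9L || n_minichromosomes > 20L) {
    warning("n_minichromosomes outside the observed 9-20 range")
  }
  with_seed(seed, {
    if (is.null(partition)) {
      partition <- random_gene_partition(n_minichromosomes)
    }
    if (length(partition) != n_minichromosomes) {
      stop("partition size disagrees with n_minichromosomes")
    }
    # partition must cover the vocabulary exactly once
    k0 <- parse_karyotype(partition, species = "synthetic ancestor")
    ix <- gene_index(k0)
    if (any(ix$status != "full")) {
      stop("ancestral partition must not contain pseudo genes")
    }
    cov <- table(factor(ix$name, levels = canonical_vocabulary()$name))
    if (any(cov != 1L)) {
      bad <- names(cov)[cov != 1L]
      stop("partition does not cover the vocabulary exactly once: ",
           paste(bad, collapse = ", "))
    }

    ncr_n <- if (length(ncr_len) == 1L) as.integer(ncr_len) else
      sample(seq(as.integer(ncr_len[1L]), as.integer(ncr_len[2L])), 1L)
    at_seq <- .motif_seq(motif_spec$at$len, gc = 1 - motif_spec$at$at_frac)
    gc_seq <- .motif_seq(motif_spec$gc$len, gc = motif_spec$gc$gc_frac)
    need <- motif_spec$at$len + motif_spec$gc$len + 40L
    if (ncr_n < need) {
      stop("ncr_len too short for the planted motifs (need >= ", need, ")")
    }
    # NCR runs downstream of the cluster around to the next cluster
    # start: GC motif sits in the first (downstream) part, AT motif in
    # the last (upstream) part
    gc_at <- max(1L, as.integer(round(0.08 * ncr_n)))
    at_at <- ncr_n - motif_spec$at$len + 1L -
      max(0L, as.integer(round(0.05 * ncr_n)))
    ncr_seq <- random_seq(ncr_n, gc)
    substr(ncr_seq, gc_at, gc_at + motif_spec$gc$len - 1L) <- gc_seq
    substr(ncr_seq, at_at, at_at + motif_spec$at$len - 1L) <- at_seq

    motif_pos <- c(seq(gc_at, gc_at + motif_spec$gc$len - 1L),
                   seq(at_at, at_at + motif_spec$at$len - 1L))
    background <- setdiff(seq_len(ncr_n), motif_pos)
    diverge_ncr <- function() {
      if (ncr_divergence <= 0) return(ncr_seq)
      chars <- strsplit(ncr_seq, "", fixed = TRUE)[[1L]]
      hit <- background[stats::runif(length(background)) < ncr_divergence]
      for (p in hit) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      paste(chars, collapse = "")
    }

    chroms <- lapply(k0$minichromosomes, function(m) {
      g <- m$genes
      g$length_bp <- as.integer(gene_lengths[g$name])
      if (attach_sequences) {
        g$sequence <- vapply(g$length_bp, random_seq, character(1L),
                             gc = gc)
        minichromosome(
          g,
          cluster_len_bp = sum(g$length_bp),
          ncr_len_bp = ncr_n,
          total_len_bp = sum(g$length_bp) + ncr_n,
          pseudo_len_bp = 0L,
          ncr_sequence = diverge_ncr(),
          cluster_sequence = paste(g$sequence, collapse = "")
        )
      } else {
        minichromosome(g,
                       cluster_len_bp = sum(g$length_bp),
                       ncr_len_bp = ncr_n,
                       total_len_bp = sum(g$length_bp) + ncr_n,
                       pseudo_len_bp = 0L)
      }
    })
    motifs <- data.frame(
      name = c("AT", "GC"),
      sequence = c(at_seq, gc_seq),
      length_bp = c(motif_spec$at$len, motif_spec$gc$len),
      position_class = c("upstream_of_cluster", "downstream_of_cluster"),
      offset = c(at_at, gc_at),
      stringsAsFactors = FALSE
    )
    structure(list(
      karyotype = karyotype(unname(chroms), species = "synthetic ancestor"),
      ncr_sequence = if (attach_sequences) ncr_seq else NA_character_,
      motifs = motifs,
      seed = seed,
      params = list(gc = gc, ncr_len = ncr_n,
                    ncr_divergence = ncr_divergence,
                    gene_lengths = gene_lengths)
    ), class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic genome> %d minichromosomes, NCR %d bp, seed %s\n",
              length(x$karyotype$minichromosomes), x$params$ncr_len,
              format(x$seed)))
  invisible(x)
}

#' Circle sequences of a synthetic genome
#'
#' @param genome A `synthetic_genome`.
#' @return Named character vector: minichromosome label to full circular
#'   sequence, linearized at the NCR cut (cluster first, then NCR).
#' @export
genome_circles <- function(genome) {
  stopifnot(inherits(genome, "synthetic_genome"))
  vapply(genome$karyotype$minichromosomes, function(m) {
    paste0(m$cluster_sequence, m$ncr_sequence)
  }, character(1L))
}

#' Write a synthetic genome as FASTA
#'
#' One record per minichromosome, linearized at the NCR cut.
#'
#' @param genome A `synthetic_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  circles <- genome_circles(genome)
  set <- Biostrings::DNAStringSet(circles)
  names(set) <- names(circles)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
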