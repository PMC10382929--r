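# Toy iterative map-to-reference assembler for minichromosomal genomes:
# read filtering, seed-and-extend of one minichromosome with
# circularization, shared-NCR consensus between two seed assemblies,
# and NCR-bait recovery of the remaining minichromosomes.
#
# Overlap identity is exact matches / overlap length (no gaps inside
# read overlaps; the simulator's error model is substitution-only), and
# extension consensus is the strict-majority base per column, so the
# assembler stalls rather than guesses at genuinely ambiguous branch
# points (e.g. the shared-NCR to cluster junctions when reads from many
# minichromosomes are mixed).  Defaults follow the emulated study
# protocol (300 bp reads, 530 bp inserts, minimum overlap 200 bp at 99%
# identity) but are configurable so that desk-scale toys run in
# seconds.

#' Quality- and N-filter paired reads
#'
#' Removes a read pair when either mate contains more than
#' `max_n_frac` ambiguous bases (`N`) or more than `max_lowq_frac` of
#' its bases at or below Phred quality `q_thresh` (Phred+33 encoding).
#' Order is otherwise preserved, and the operation is idempotent.
#'
#' @param pairs A read-pair data frame (`read1`, `qual1`, `read2`,
#'   `qual2`), e.g. from [simulate_reads()] or [read_fastq_pairs()].
#' @param max_n_frac Maximum tolerated fraction of `N` bases (default
#'   0.10).
#' @param q_thresh Phred threshold defining a low-quality base (default
#'   20).
#' @param max_lowq_frac Maximum tolerated fraction of bases with
#'   quality at or below `q_thresh` (default 0.50).
#' @return The filtered data frame.
#' @export
filter_reads <- function(pairs, max_n_frac = 0.10, q_thresh = 20L,
                         max_lowq_frac = 0.50) {
  stopifnot(is.data.frame(pairs),
            all(c("read1", "qual1", "read2", "qual2") %in% names(pairs)))
  n_frac <- function(s) {
    (nchar(s) - nchar(gsub("N", "", s, fixed = TRUE))) / pmax(nchar(s), 1L)
  }
  lowq_frac <- function(q) {
    vapply(q, function(x) {
      mean(utf8ToInt(x) - 33L <= q_thresh)
    }, numeric(1L))
  }
  bad <- n_frac(pairs$read1) > max_n_frac |
    n_frac(pairs$read2) > max_n_frac |
    lowq_frac(pairs$qual1) > max_lowq_frac |
    lowq_frac(pairs$qual2) > max_lowq_frac
  pairs[!bad, , drop = FALSE]
}

# flatten a read source (character vector or pair data frame) into a
# DNAStringSet holding each read and its reverse complement
.read_set <- function(reads) {
  seqs <- if (is.data.frame(reads)) c(reads$read1, reads$read2) else
    as.character(reads)
  set <- Biostrings::DNAStringSet(seqs)
  c(set, Biostrings::reverseComplement(set))
}

.mm_allowed <- function(m, min_identity) {
  as.integer(floor((1 - min_identity) * m))
}

# per-read window hits: data.frame(read = index into subj, start)
.window_hits <- function(window, subj, mm) {
  m <- Biostrings::vmatchPattern(window, subj, max.mismatch = mm,
                                 with.indels = FALSE, fixed = TRUE)
  starts <- Biostrings::startIndex(m)
  hit <- which(lengths(starts) > 0L)
  if (length(hit) == 0L) {
    return(data.frame(read = integer(), start = integer()))
  }
  data.frame(read = rep(hit, lengths(starts[hit])),
             start = unlist(starts[hit], use.names = FALSE))
}

# supermajority consensus over a list of extension strings (aligned at
# column 1); stops at the first column whose leading base falls below
# `consensus_frac` of the votes (or below `min_support` votes).  The
# supermajority - rather than a bare majority - makes extension stall
# at genuinely ambiguous branch points, e.g. the shared-NCR to
# gene-cluster junctions where reads from different minichromosomes
# diverge, instead of following whichever minichromosome happens to
# have the most reads locally.
.majority_extension <- function(exts, min_support = 1L,
                                consensus_frac = 0.7) {
  exts <- exts[nchar(exts) > 0L]
  if (length(exts) == 0L) return("")
  mat <- vapply(exts, function(e) {
    c(strsplit(e, "", fixed = TRUE)[[1L]],
      rep(NA_character_, max(nchar(exts)) - nchar(e)))
  }, character(max(nchar(exts))))
  mat <- matrix(mat, nrow = max(nchar(exts)))
  out <- character(0L)
  votes <- integer(0L)
  for (j in seq_len(nrow(mat))) {
    col <- mat[j, !is.na(mat[j, ])]
    if (length(col) < min_support) break
    tab <- sort(table(col), decreasing = TRUE)
    if (tab[1L] * 2L <= length(col) ||
          tab[1L] < consensus_frac * length(col)) break
    out <- c(out, names(tab)[1L])
    votes <- c(votes, as.integer(tab[1L]))
  }
  structure(paste(out, collapse = ""), votes = votes)
}

# largest prefix/suffix self-overlap v >= min_overlap at >= min_identity
# (candidates located via occurrences of the terminal window near the
# contig start); 0 when none
.self_overlap <- function(contig, min_overlap, min_identity) {
  L <- nchar(contig)
  if (L < 2L * min_overlap) return(0L)
  m <- min_overlap
  mm <- .mm_allowed(m, min_identity)
  tail_w <- substr(contig, L - m + 1L, L)
  hits <- Biostrings::matchPattern(tail_w,
                                   Biostrings::DNAString(substr(contig, 1L,
                                                                L - 1L)),
                                   max.mismatch = mm, with.indels = FALSE)
  ends <- BiocGenerics::end(hits)
  cand <- sort(unique(ends[ends >= m & ends < L]), decreasing = TRUE)
  for (v in cand) {
    a <- strsplit(substr(contig, 1L, v), "", fixed = TRUE)[[1L]]
    b <- strsplit(substr(contig, L - v + 1L, L), "", fixed = TRUE)[[1L]]
    if (mean(a == b) >= min_identity) return(as.integer(v))
  }
  0L
}

#' Iterative seed-and-extend assembly of one minichromosome
#'
#' Starting from a seed sequence (e.g. one gene), repeatedly recruits
#' reads whose overlap with a contig end covers the terminal
#' `min_overlap` bases at `min_identity` or better, extends the contig
#' by the strict-majority consensus of the recruited reads (both
#' directions), and stops at a fixpoint.  The contig is declared
#' circular as soon as its two ends mutually overlap by at least
#' `min_overlap` at `min_identity`, in which case the duplicated
#' overlap is trimmed.
#'
#' @param reads A character vector of reads or a read-pair data frame;
#'   both strands are searched.
#' @param seed_sequence Seed (length at least `min_overlap`).
#' @param min_overlap Minimum end overlap in bp (default 200).
#' @param min_identity Minimum overlap identity (default 0.99); exact
#'   matches over overlap length, substitution-only.
#' @param min_support Minimum reads supporting an extension column.
#' @param consensus_frac Minimum fraction of column votes the leading
#'   base must reach for the extension to proceed (default 0.7);
#'   extension stalls at branch points where recruited reads disagree.
#' @param max_rounds,max_length Safety caps.
#' @param provenance Free-text provenance tag stored on the contig.
#' @return An object of class `contig`: `sequence`, `circular`,
#'   `depth` (approximate per-extended-column support), `provenance`.
#' @export
iterative_extend <- function(reads, seed_sequence, min_overlap = 200L,
                             min_identity = 0.99, min_support = 1L,
                             consensus_frac = 0.7,
                             max_rounds = 1000L, max_length = 200000L,
                             provenance = "seed") {
  seed_sequence <- toupper(seed_sequence)
  if (nchar(seed_sequence) < min_overlap) {
    stop("seed_sequence shorter than min_overlap")
  }
  subj <- .read_set(reads)
  mm <- .mm_allowed(min_overlap, min_identity)
  contig <- seed_sequence
  circular <- FALSE
  depth <- integer(0L)
  first_round <- TRUE

  for (round in seq_len(max_rounds)) {
    L <- nchar(contig)
    # rightward
    win_r <- substr(contig, L - min_overlap + 1L, L)
    hits_r <- .window_hits(win_r, subj, mm)
    exts_r <- character(0L)
    if (nrow(hits_r)) {
      exts_r <- substr(as.character(subj[hits_r$read]),
                       hits_r$start + min_overlap, .Machine$integer.max)
    }
    ext_r <- .majority_extension(exts_r, min_support, consensus_frac)
    # leftward (extensions reversed so column 1 abuts the contig)
    win_l <- substr(contig, 1L, min_overlap)
    hits_l <- .window_hits(win_l, subj, mm)
    exts_l <- character(0L)
    if (nrow(hits_l)) {
      lefts <- substr(as.character(subj[hits_l$read]), 1L,
                      hits_l$start - 1L)
      exts_l <- vapply(lefts, function(s) {
        paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
      }, character(1L), USE.NAMES = FALSE)
    }
    ext_l <- .majority_extension(exts_l, min_support, consensus_frac)

    if (first_round && nrow(hits_r) == 0L && nrow(hits_l) == 0L) {
      stop("seed not covered")
    }
    first_round <- FALSE

    grew <- FALSE
    if (nchar(ext_r) > 0L) {
      contig <- paste0(contig, ext_r)
      depth <- c(depth, attr(ext_r, "votes"))
      grew <- TRUE
    }
    if (nchar(ext_l) > 0L) {
      rev_l <- paste(rev(strsplit(ext_l, "", fixed = TRUE)[[1L]]),
                     collapse = "")
      contig <- paste0(rev_l, contig)
      depth <- c(rev(attr(ext_l, "votes")), depth)
      grew <- TRUE
    }

    v <- .self_overlap(contig, min_overlap, min_identity)
    if (v > 0L) {
      contig <- substr(contig, 1L, nchar(contig) - v)
      circular <- TRUE
      break
    }
    if (!grew || nchar(contig) > max_length) break
  }

  structure(list(sequence = contig, circular = circular, depth = depth,
                 provenance = provenance),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig> %d bp, %s, provenance: %s\n", nchar(x$sequence),
              if (x$circular) "circular" else "linear", x$provenance))
  invisible(x)
}

#' Shared-NCR consensus between two circular contigs
#'
#' Locates the longest region shared at `min_identity` or better
#' between two assembled circles - for minichromosomal genomes, the
#' conserved large NCR.  An exact longest common substring (computed on
#' the doubled circles, both strands) anchors the region, which is then
#' extended outwards across *isolated* mismatches only (a mismatch is
#' absorbed when the following ten columns match, so extension stops at
#' local divergence such as the junctions into the flanking gene
#' clusters) while overall identity stays at or above `min_identity`;
#' the region is finally trimmed back to matching columns and by
#' `end_trim` additional bases per end to guard against chance matches
#' running past the junctions.
#'
#' @param contig_a,contig_b Circular `contig` objects (or plain
#'   sequences).
#' @param min_overlap Minimum acceptable shared-region length.
#' @param min_identity Identity threshold.
#' @param end_trim Bases trimmed from each end of the shared region.
#' @return The consensus sequence (bases taken from `contig_a`), in the
#'   genome-forward orientation of `contig_a`, with attributes `pos_a`
#'   and `length`.
#' @export
derive_ncr_consensus <- function(contig_a, contig_b, min_overlap = 200L,
                                 min_identity = 0.99, end_trim = 8L) {
  seq_of <- function(x, arg) {
    if (inherits(x, "contig")) {
      if (!x$circular) stop(arg, " is not circular")
      x$sequence
    } else toupper(as.character(x))
  }
  a <- seq_of(contig_a, "contig_a")
  b <- seq_of(contig_b, "contig_b")
  La <- nchar(a); Lb <- nchar(b)
  a2 <- paste0(a, a)
  hit <- NULL
  for (bb in c(b, revcomp(b))) {
    b2 <- paste0(bb, bb)
    h <- longest_shared_stretch(a2, b2)
    if (is.null(hit) || h$length_bp > hit$length_bp) hit <- h
  }
  if (hit$length_bp < min_overlap %/% 2L) {
    stop("no shared region of usable length between the two contigs")
  }
  b2 <- paste0(b, b)  # orientation of the winning strand
  # re-anchor on the winning orientation
  fw <- longest_shared_stretch(a2, b2)
  rcb <- revcomp(b)
  rc <- longest_shared_stretch(a2, paste0(rcb, rcb))
  use_rc <- rc$length_bp > fw$length_bp
  hit <- if (use_rc) rc else fw
  bseq2 <- if (use_rc) paste0(rcb, rcb) else b2

  av <- strsplit(a2, "", fixed = TRUE)[[1L]]
  bv <- strsplit(bseq2, "", fixed = TRUE)[[1L]]
  sa <- hit$pos_a; sb <- hit$pos_b
  ea <- sa + hit$length_bp - 1L; eb <- sb + hit$length_bp - 1L
  span_cap <- min(La, Lb)

  matches <- hit$length_bp; total <- hit$length_bp
  look <- 10L
  # extend right across isolated mismatches only
  while (ea < 2L * La && eb < 2L * Lb && total < span_cap) {
    if (av[ea + 1L] != bv[eb + 1L]) {
      ahead <- seq_len(look)
      if (ea + 1L + look > 2L * La || eb + 1L + look > 2L * Lb ||
            !all(av[ea + 1L + ahead] == bv[eb + 1L + ahead]) ||
            matches / (total + 1L) < min_identity) break
    } else matches <- matches + 1L
    ea <- ea + 1L; eb <- eb + 1L
    total <- total + 1L
  }
  # extend left across isolated mismatches only
  while (sa > 1L && sb > 1L && total < span_cap) {
    if (av[sa - 1L] != bv[sb - 1L]) {
      ahead <- seq_len(look)
      if (sa - 1L - look < 1L || sb - 1L - look < 1L ||
            !all(av[sa - 1L - ahead] == bv[sb - 1L - ahead]) ||
            matches / (total + 1L) < min_identity) break
    } else matches <- matches + 1L
    sa <- sa - 1L; sb <- sb - 1L
    total <- total + 1L
  }
  # trim back to matching end columns, then the safety trim
  while (ea > sa && av[ea] != bv[eb]) { ea <- ea - 1L; eb <- eb - 1L }
  while (sa < ea && av[sa] != bv[sb]) { sa <- sa + 1L; sb <- sb + 1L }
  sa2 <- sa + end_trim; ea2 <- ea - end_trim
  if (ea2 - sa2 + 1L < min_overlap) {
    stop("shared region shorter than min_overlap after trimming (",
         ea2 - sa2 + 1L, " bp)")
  }
  structure(substr(a2, sa2, ea2),
            pos_a = ((sa2 - 1L) %% La) + 1L,
            length = ea2 - sa2 + 1L)
}

#' NCR-bait recovery of all minichromosomes
#'
#' Uses the conserved shared-NCR consensus as bait: reads matching the
#' downstream end of the consensus and running on into a gene cluster
#' are grouped by their flanking sequence (one group per distinct
#' cluster head, i.e. per minichromosome), and each group seeds one
#' [iterative_extend()] assembly.  With the shared NCR as part of every
#' seed, each extension circularizes through its own gene cluster
#' before reaching any ambiguous junction.  The number of distinct
#' circular contigs recovered is the assembler's estimate of the
#' minichromosome count.
#'
#' @param reads A character vector of reads or a read-pair data frame.
#' @param ncr_consensus Consensus from [derive_ncr_consensus()] (or any
#'   sequence inside the conserved NCR reaching its downstream end).
#' @param min_overlap,min_identity,min_support As in
#'   [iterative_extend()].
#' @param flank_len Length of the cluster-head flank used to separate
#'   minichromosomes.
#' @param min_flank_support Minimum reads supporting a flank group.
#' @return A list of `contig` objects (circular ones first), with
#'   attribute `n_minichromosomes` = number of distinct circular
#'   contigs.
#' @export
bait_assemble <- function(reads, ncr_consensus, min_overlap = 200L,
                          min_identity = 0.99, min_support = 1L,
                          flank_len = 30L, min_flank_support = 2L) {
  ncr_consensus <- toupper(as.character(ncr_consensus))
  if (!nzchar(ncr_consensus)) stop("empty NCR consensus")
  subj <- .read_set(reads)
  m <- min_overlap
  if (nchar(ncr_consensus) < m) stop("NCR consensus shorter than min_overlap")
  mm <- .mm_allowed(m, min_identity)
  Lc <- nchar(ncr_consensus)
  tail_w <- substr(ncr_consensus, Lc - m + 1L, Lc)
  hits <- .window_hits(tail_w, subj, mm)
  if (nrow(hits) == 0L) return(structure(list(), n_minichromosomes = 0L))
  rlen <- nchar(as.character(subj[hits$read]))
  keep <- hits$start + m + flank_len - 1L <= rlen
  hits <- hits[keep, , drop = FALSE]
  flanks <- substr(as.character(subj[hits$read]), hits$start + m,
                   hits$start + m + flank_len - 1L)

  # group flanks: assign to an existing group within a small Hamming
  # distance (sequencing errors), most frequent flank first
  tol <- max(1L, as.integer(ceiling(flank_len * (1 - min_identity) * 3)))
  hamming <- function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1L]] !=
          strsplit(y, "", fixed = TRUE)[[1L]])
  }
  tab <- sort(table(flanks), decreasing = TRUE)
  groups <- character(0L); support <- integer(0L)
  for (fl in names(tab)) {
    d <- vapply(groups, hamming, integer(1L), y = fl)
    if (length(d) && min(d) <= tol) {
      support[which.min(d)] <- support[which.min(d)] + tab[[fl]]
    } else {
      groups <- c(groups, fl)
      support <- c(support, tab[[fl]])
    }
  }
  groups <- groups[support >= min_flank_support]

  contigs <- list()
  for (fl in groups) {
    ctg <- tryCatch(
      iterative_extend(reads, paste0(ncr_consensus, fl),
                       min_overlap = min_overlap,
                       min_identity = min_identity,
                       min_support = min_support, provenance = "baited"),
      error = function(e) NULL)
    if (is.null(ctg)) next
    dup <- any(vapply(contigs, function(x) {
      x$circular && ctg$circular &&
        rotation_equivalent(x$sequence, ctg$sequence)
    }, logical(1L)))
    if (!dup) contigs[[length(contigs) + 1L]] <- ctg
  }
  circ <- vapply(contigs, `[[`, logical(1L), "circular")
  contigs <- contigs[order(!circ)]
  structure(contigs, n_minichromosomes = sum(circ))
}

#' Write contigs as FASTA with a JSON assembly report
#'
#' Circular contigs are canonicalized by rotation: cut at the position
#' of the NCR consensus start when one is supplied and found, else at
#' the lexicographically minimal rotation.
#'
#' @param contigs A list of `contig` objects.
#' @param fasta_path Output FASTA path.
#' @param report_path Optional JSON report path (per-contig length,
#'   circular flag, provenance, mean depth).
#' @param ncr_consensus Optional NCR consensus used for rotation
#'   canonicalization.
#' @return `fasta_path`, invisibly.
#' @export
write_contigs <- function(contigs, fasta_path, report_path = NULL,
                          ncr_consensus = NULL) {
  canon <- function(ctg) {
    s <- ctg$sequence
    if (!ctg$circular) return(s)
    d <- paste0(s, s)
    if (!is.null(ncr_consensus)) {
      p <- regexpr(ncr_consensus, d, fixed = TRUE)
      if (p > 0L) return(substr(d, p, p + nchar(s) - 1L))
    }
    rots <- vapply(seq_len(nchar(s)), function(i) {
      substr(d, i, i + nchar(s) - 1L)
    }, character(1L))
    min(rots)
  }
  seqs <- vapply(contigs, canon, character(1L))
  names(seqs) <- sprintf("contig_%02d_%s%s", seq_along(seqs),
                         vapply(contigs, `[[`, character(1L), "provenance"),
                         ifelse(vapply(contigs, `[[`, logical(1L),
                                       "circular"), "_circular", ""))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, fasta_path)
  if (!is.null(report_path)) {
    rep <- lapply(seq_along(contigs), function(i) {
      ctg <- contigs[[i]]
      list(name = names(seqs)[i], length_bp = nchar(ctg$sequence),
           circular = ctg$circular, provenance = ctg$provenance,
           mean_depth = if (length(ctg$depth)) mean(ctg$depth) else NA)
    })
    writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, na = "null",
                                digits = NA), report_path)
  }
  invisible(fasta_path)
}
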