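# Sequence-level evidence for inter-minichromosomal recombination:
# alignment percent difference between gene copies, longest shared
# identical stretch between sequences (with a Monte Carlo chance null),
# and conserved NCR motif discovery.

.check_nt <- function(x, arg) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L) {
    stop(arg, " must be a non-empty nucleotide string")
  }
  if (grepl("[^ACGTNacgtn]", x)) {
    stop(arg, " contains characters outside {A,C,G,T,N}")
  }
  toupper(x)
}

#' Percent sequence difference between two gene copies
#'
#' Globally aligns the two sequences end to end (Needleman-Wunsch via
#' [Biostrings::pairwiseAlignment()]; match +1, mismatch -1, gap -2 per
#' column by default) and reports the percentage of alignment columns
#' that are mismatches or gaps.  Gap columns count as differences and
#' the denominator is the alignment length; this convention is recorded
#' in the result's attributes because published per-gene percentages do
#' not state theirs.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param match,mismatch,gap Alignment scores (gap is the per-column gap
#'   penalty, given as a positive cost).
#' @return Percent difference in `[0, 100]`, with attributes
#'   `alignment_length`, `mismatches`, `gaps`, and `scoring`.
#' @export
#' @examples
#' percent_difference("ACGT", "ACGA")  # 25
percent_difference <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  a <- .check_nt(a, "a"); b <- .check_nt(b, "b")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = gap)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  gaps <- sum(pa == "-" | sa == "-")
  mism <- sum(pa != sa & pa != "-" & sa != "-")
  len <- length(pa)
  structure(100 * (mism + gaps) / len,
            alignment_length = len, mismatches = mism, gaps = gaps,
            scoring = c(match = match, mismatch = mismatch, gap = gap))
}

# longest common substring of two strings via the classical
# dynamic-programming recurrence, vectorized one row at a time:
# L[i, j] = (a[i] == b[j]) * (L[i-1, j-1] + 1).
# Returns list(length, pos_a, pos_b) with the tie-break: smallest start
# in a, then smallest start in b.
.lcs_dp <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  prev <- integer(m)
  best_len <- 0L; best_a <- 0L; best_b <- 0L
  for (i in seq_len(n)) {
    cur <- ifelse(bv == av[i], c(0L, prev[-m]) + 1L, 0L)
    mx <- max(cur)
    if (mx > best_len) {
      j <- which.max(cur)
      best_len <- mx
      best_a <- i - mx + 1L
      best_b <- j - mx + 1L
    }
    prev <- cur
  }
  list(length = best_len, pos_a = best_a, pos_b = best_b)
}

#' Longest shared identical stretch between two sequences
#'
#' Finds a maximal-length exact common substring between `a` and `b`,
#' optionally also scanning the reverse complement of `b`.  Stretches of
#' identical sequence between genes on different minichromosomes, much
#' longer than expected by chance (see [stretch_null_quantile()]), are
#' the classical signature of inter-minichromosomal recombination.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param include_revcomp Also search the reverse complement of `b`.
#' @return An object of class `stretch_hit`: a list with `length_bp`,
#'   `pos_a`, `pos_b` (1-based start positions; `pos_b` is on the
#'   original `b` coordinates), `strand` (`"same"` or `"revcomp"`), and
#'   `sequence`.  A zero-length sentinel hit is returned when the
#'   sequences share no character.  Ties are broken by smallest `pos_a`,
#'   then smallest `pos_b`, with the same-strand hit preferred.
#' @export
longest_shared_stretch <- function(a, b, include_revcomp = FALSE) {
  a <- .check_nt(a, "a"); b <- .check_nt(b, "b")
  fw <- .lcs_dp(a, b)
  hit <- list(length_bp = fw$length, pos_a = fw$pos_a, pos_b = fw$pos_b,
              strand = "same")
  if (include_revcomp) {
    rc <- .lcs_dp(a, revcomp(b))
    better <- rc$length > hit$length_bp ||
      (rc$length == hit$length_bp && rc$length > 0L &&
         (rc$pos_a < hit$pos_a))
    if (better) {
      # map the start in revcomp(b) back to original b coordinates
      pos_b <- nchar(b) - (rc$pos_b + rc$length - 1L) + 1L
      hit <- list(length_bp = rc$length, pos_a = rc$pos_a, pos_b = pos_b,
                  strand = "revcomp")
    }
  }
  hit$sequence <- if (hit$length_bp > 0L) {
    substr(a, hit$pos_a, hit$pos_a + hit$length_bp - 1L)
  } else ""
  structure(hit, class = "stretch_hit")
}

#' @export
print.stretch_hit <- function(x, ...) {
  cat(sprintf("<stretch hit> %d bp at a:%d / b:%d (%s strand)\n",
              x$length_bp, x$pos_a, x$pos_b, x$strand))
  invisible(x)
}

#' Chance null for shared-stretch lengths
#'
#' Monte Carlo null model for [longest_shared_stretch()]: simulates
#' `reps` independent pairs of iid multinomial sequences at the given
#' lengths and GC content, records the maximal shared stretch of each
#' pair, and returns the empirical `q` quantile.  An observed stretch
#' above this threshold is longer than expected by chance at that
#' level.  The null is iid by composition; no Markov-order correction is
#' applied (a declared limitation).
#'
#' @param len_a,len_b Sequence lengths.
#' @param gc GC fraction in `[0, 1]`.
#' @param reps Number of simulated pairs (at least 100).
#' @param q Quantile in `[0, 1]`.
#' @param seed Integer seed; results are reproducible under it.
#' @param include_revcomp Match the search mode of the observed hit.
#' @return The empirical quantile of null stretch lengths (type-1
#'   quantile, an observed order statistic).
#' @export
stretch_null_quantile <- function(len_a, len_b, gc = 0.5, reps = 1000,
                                  q = 0.99, seed = 1,
                                  include_revcomp = FALSE) {
  stopifnot(len_a >= 1L, len_b >= 1L)
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (!is.numeric(q) || q < 0 || q > 1) stop("q must be in [0, 1]")
  if (reps < 100L) stop("reps must be at least 100")
  lens <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      a <- random_seq(len_a, gc)
      b <- random_seq(len_b, gc)
      longest_shared_stretch(a, b, include_revcomp)$length_bp
    }, integer(1L))
  })
  as.numeric(stats::quantile(lens, q, type = 1L, names = FALSE))
}

# maximal match length at every start position of `pivot`: f[i] is the
# largest L such that substr(pivot, i, i+L-1) occurs in every string of
# `others` (0 when even the single character does not).  Monotone in L
# for fixed i, so each f[i] is found by binary search over L with
# fixed-string containment tests.
.common_prefix_lengths <- function(pivot, others) {
  n <- nchar(pivot)
  occurs_all <- function(s) all(vapply(others, grepl, logical(1L),
                                       pattern = s, fixed = TRUE))
  vapply(seq_len(n), function(i) {
    lo <- 0L; hi <- n - i + 1L
    while (lo < hi) {
      mid <- as.integer(ceiling((lo + hi) / 2))
      if (occurs_all(substr(pivot, i, i + mid - 1L))) lo <- mid else
        hi <- mid - 1L
    }
    lo
  }, integer(1L))
}

#' Find motifs conserved across all supplied NCRs
#'
#' Reports the maximal exact substrings shared by *every* supplied
#' non-coding region, of length at least `min_len`: every returned
#' motif occurs in all NCRs and is not extendable (it is not contained
#' in a longer substring that is also common to all).  Each motif is
#' annotated with its AT fraction and a position class: NCR sequences
#' are read in genome orientation from the end of the gene cluster
#' around to the start of the next cluster, so occurrences in the first
#' half of an NCR lie downstream of the cluster and occurrences in the
#' second half lie upstream of the (next) cluster; the class is decided
#' by majority across NCRs.  Degenerate (mismatch-tolerant) motifs are
#' out of scope.
#'
#' @param ncrs A character vector (or list) of at least two NCR
#'   sequences.
#' @param min_len Minimum motif length to report.
#' @return A data frame of class `motif_hits`, ordered by length
#'   descending (ties by consensus string): columns `consensus`,
#'   `length_bp`, `AT_fraction`, `position_class`, and `offsets` (a list
#'   column of 1-based start offsets, one per NCR).  Empty (zero rows)
#'   when nothing of length `min_len` is shared.
#' @export
find_conserved_motifs <- function(ncrs, min_len = 20L) {
  ncrs <- vapply(ncrs, function(x) .check_nt(x, "ncr"), character(1L))
  if (length(ncrs) < 2L) stop("need at least two NCR sequences")
  pivot_i <- which.min(nchar(ncrs))
  pivot <- ncrs[pivot_i]
  others <- ncrs[-pivot_i]
  f <- .common_prefix_lengths(pivot, others)
  n <- length(f)
  # right-maximal by construction of f; left-maximal unless the
  # stretch starting one position earlier extends one longer
  starts <- which(f >= min_len &
                    (seq_len(n) == 1L | c(0L, f[-n]) != f + 1L))
  if (length(starts) == 0L) {
    out <- data.frame(consensus = character(), length_bp = integer(),
                      AT_fraction = numeric(), position_class = character(),
                      stringsAsFactors = FALSE)
    out$offsets <- list()
    class(out) <- c("motif_hits", "data.frame")
    return(out)
  }
  motifs <- unique(substr(rep(pivot, length(starts)), starts,
                          starts + f[starts] - 1L))
  # drop motifs contained in another (longer) reported motif
  contained <- vapply(seq_along(motifs), function(i) {
    any(nchar(motifs) > nchar(motifs[i]) &
          vapply(motifs, grepl, logical(1L), pattern = motifs[i],
                 fixed = TRUE))
  }, logical(1L))
  motifs <- motifs[!contained]
  hits <- lapply(motifs, function(s) {
    offs <- vapply(ncrs, function(x) {
      as.integer(regexpr(s, x, fixed = TRUE))
    }, integer(1L))
    # position class: first vs second half of each NCR, majority vote
    mid_frac <- (offs + nchar(s) / 2) / nchar(ncrs)
    class_votes <- ifelse(mid_frac <= 0.5, "downstream_of_cluster",
                          "upstream_of_cluster")
    data.frame(
      consensus = s, length_bp = nchar(s), AT_fraction = at_fraction(s),
      position_class = names(sort(table(class_votes),
                                  decreasing = TRUE))[1L],
      stringsAsFactors = FALSE
    ) -> row
    row$offsets <- list(unname(offs))
    row
  })
  out <- do.call(rbind, hits)
  out <- out[order(-out$length_bp, out$consensus), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Pairwise shared-stretch table for a set of gene sequences
#'
#' Convenience wrapper running [longest_shared_stretch()] over all
#' sequence pairs, as used when screening genes on different
#' minichromosomes for recombination evidence.
#'
#' @param seqs A named character vector of sequences.
#' @param include_revcomp Also search reverse complements.
#' @return A data frame: `seq_a`, `seq_b`, `length_bp`, `pos_a`,
#'   `pos_b`, `strand`.
#' @export
stretch_table <- function(seqs, include_revcomp = FALSE) {
  stopifnot(is.character(seqs), length(seqs) >= 2L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  pairs <- utils::combn(names(seqs), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    hit <- longest_shared_stretch(seqs[[pairs[1L, i]]],
                                  seqs[[pairs[2L, i]]], include_revcomp)
    data.frame(seq_a = pairs[1L, i], seq_b = pairs[2L, i],
               length_bp = hit$length_bp, pos_a = hit$pos_a,
               pos_b = hit$pos_b, strand = hit$strand,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
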