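# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' Plain character interface around [Biostrings::reverseComplement()];
#' accepts the alphabet `{A,C,G,T,N}`.
#'
#' @param x A single nucleotide string.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Run `code` under a fixed RNG state without disturbing the caller's
# stream.  All stochastic operations in the package funnel through this
# so results are reproducible under a single integer seed.  R's default
# Mersenne-Twister has integer state and identical behaviour across
# platforms.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Random nucleotide string of length n at a given GC fraction.
random_seq <- function(n, gc = 0.3) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Test two circular sequences for rotation equivalence
#'
#' Two strings are rotation-equivalent when one is a cyclic rotation of
#' the other, optionally also checking the reverse-complement strand.
#' Used to compare assembled circular contigs against truth sequences,
#' whose linearization cut point is arbitrary.
#'
#' @param a,b Nucleotide strings representing circular sequences.
#' @param both_strands Also accept a rotation of the reverse complement.
#' @return `TRUE` or `FALSE`.
#' @export
rotation_equivalent <- function(a, b, both_strands = TRUE) {
  stopifnot(is.character(a), is.character(b))
  if (nchar(a) != nchar(b)) return(FALSE)
  if (nchar(a) == 0L) return(TRUE)
  if (grepl(a, paste0(b, b), fixed = TRUE)) return(TRUE)
  both_strands && grepl(a, paste0(revcomp(b), revcomp(b)), fixed = TRUE)
}

# Fraction of A/T characters in a string (N ignored in the denominator
# only when the string is all N).
at_fraction <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(NA_real_)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  sum(chars %in% c("A", "T", "a", "t")) / n
}
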