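# Paired-end read simulation over circular minichromosomes, and plain
# FASTQ input/output.  The error model is substitution-only (no indels,
# no GC bias); qualities are constant Q37 by default, with a
# degraded-tail mode that exists solely to exercise the read filter.

.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(s)
  pos <- sample.int(n, k)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate paired-end reads from a synthetic genome
#'
#' Uniform circular sampling per minichromosome: the number of pairs per
#' circle is `round(coverage * circle_len / (2 * read_len))`, fragment
#' start positions are uniform on the circle, and fragments come from
#' either strand.  Mate 1 is the first `read_len` bases of the
#' fragment; mate 2 is the reverse complement of its last `read_len`
#' bases (standard FR orientation).  Substitution errors are iid at
#' `error_rate`.  Deterministic under `seed`.
#'
#' @param genome A `synthetic_genome` with sequences attached.
#' @param coverage Target fold coverage per minichromosome.
#' @param read_len Read length in bp (default 300, the paired-end
#'   sequencing configuration emulated here).
#' @param insert_len Insert (fragment) length in bp (default 530).
#' @param error_rate Per-base substitution error probability.
#' @param quality_mode `"constant"` (Q37 throughout) or
#'   `"degraded_tail"` (last 60% of each read at Q2, for testing the
#'   quality filter).
#' @param seed Integer seed.
#' @return A data frame of read pairs: `id`, `read1`, `qual1`, `read2`,
#'   `qual2`, and the origin columns `chrom`, `offset` (1-based
#'   fragment start on the linearized circle), `strand` (`"+"`/`"-"`).
#' @export
simulate_reads <- function(genome, coverage = 30, read_len = 300L,
                           insert_len = 530L, error_rate = 0,
                           quality_mode = c("constant", "degraded_tail"),
                           seed = 1L) {
  quality_mode <- match.arg(quality_mode)
  stopifnot(coverage > 0)
  if (insert_len < read_len) stop("insert_len must be >= read_len")
  circles <- genome_circles(genome)
  short <- nchar(circles) < insert_len
  if (any(short)) {
    stop("insert_len exceeds circle length for: ",
         paste(names(circles)[short], collapse = ", "))
  }
  with_seed(seed, {
    out <- lapply(names(circles), function(lab) {
      circ <- circles[[lab]]
      L <- nchar(circ)
      doubled <- paste0(circ, circ)
      n_pairs <- max(1L, as.integer(round(coverage * L / (2 * read_len))))
      starts <- sample.int(L, n_pairs, replace = TRUE)
      strands <- sample(c("+", "-"), n_pairs, replace = TRUE)
      frags <- substr(rep(doubled, n_pairs), starts,
                      starts + insert_len - 1L)
      flip <- strands == "-"
      frags[flip] <- vapply(frags[flip], revcomp, character(1L))
      m1 <- substr(frags, 1L, read_len)
      m2 <- vapply(substr(frags, insert_len - read_len + 1L, insert_len),
                   revcomp, character(1L))
      if (error_rate > 0) {
        m1 <- vapply(m1, .mutate_seq, character(1L), rate = error_rate)
        m2 <- vapply(m2, .mutate_seq, character(1L), rate = error_rate)
      }
      data.frame(read1 = unname(m1), read2 = unname(m2), chrom = lab,
                 offset = starts, strand = strands,
                 stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, out)
    pairs$id <- sprintf("sim_%06d", seq_len(nrow(pairs)))
    qual <- if (quality_mode == "constant") {
      strrep("F", read_len)
    } else {
      head_len <- as.integer(round(read_len * 0.4))
      paste0(strrep("F", head_len), strrep("#", read_len - head_len))
    }
    pairs$qual1 <- qual
    pairs$qual2 <- qual
    rownames(pairs) <- NULL
    pairs[, c("id", "read1", "qual1", "read2", "qual2", "chrom",
              "offset", "strand")]
  })
}

#' Write read pairs to two FASTQ files
#'
#' @param pairs A read-pair data frame from [simulate_reads()] (or any
#'   data frame with `id`, `read1`, `qual1`, `read2`, `qual2`).
#' @param path1,path2 Output paths for mate 1 and mate 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq <- function(pairs, path1, path2) {
  rec <- function(seq, qual, mate) {
    as.vector(rbind(paste0("@", pairs$id, "/", mate), seq, "+", qual))
  }
  writeLines(rec(pairs$read1, pairs$qual1, 1L), path1)
  writeLines(rec(pairs$read2, pairs$qual2, 2L), path2)
  invisible(c(path1, path2))
}

.read_fastq_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': line count not a multiple of 4 ",
         "(truncated record ", length(lines) %/% 4L + 1L, ")")
  }
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  hdr <- lines[4L * idx - 3L]
  seqs <- lines[4L * idx - 2L]
  plus <- lines[4L * idx - 1L]
  quals <- lines[4L * idx]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ '", path, "': record ", bad[1L],
         " does not start with '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ '", path, "': record ", bad[1L],
         " missing '+' separator")
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("malformed FASTQ '", path, "': record ", bad[1L],
         " sequence/quality length mismatch")
  }
  data.frame(id = sub("/[12]$", "", sub("^@", "", hdr)),
             seq = toupper(seqs), qual = quals, stringsAsFactors = FALSE)
}

#' Read paired FASTQ files
#'
#' Light FASTQ parser for the simulator's output format; malformed
#' records raise an error naming the record index.
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @return A read-pair data frame (`id`, `read1`, `qual1`, `read2`,
#'   `qual2`).
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- .read_fastq_file(path1)
  r2 <- .read_fastq_file(path2)
  if (nrow(r1) != nrow(r2)) {
    stop("mate files hold different numbers of records (",
         nrow(r1), " vs ", nrow(r2), ")")
  }
  data.frame(id = r1$id, read1 = r1$seq, qual1 = r1$qual,
             read2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}
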