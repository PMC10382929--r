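# Independent oracles used to cross-check package implementations.
# Each is a deliberately naive algorithm (full DP table, exhaustive
# enumeration) kept separate from the code paths it checks.

# Needleman-Wunsch with a full DP table and traceback; returns the
# percent of alignment columns that are mismatches or gaps under
# match/mismatch/gap scoring (linear gap, per column).
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- -gap * (0:n)
  F[1, ] <- -gap * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == bv[j]) match else mismatch
      F[i + 1, j + 1] <- max(F[i, j] + s, F[i, j + 1] - gap,
                             F[i + 1, j] - gap)
    }
  }
  # traceback, preferring diagonal moves (ties resolved consistently)
  i <- n; j <- m; mism <- 0L; gaps <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    s <- if (i > 0 && j > 0 && av[i] == bv[j]) match else mismatch
    if (i > 0 && j > 0 && F[i + 1, j + 1] == F[i, j] + s) {
      if (av[i] != bv[j]) mism <- mism + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0 && F[i + 1, j + 1] == F[i, j + 1] - gap) {
      gaps <- gaps + 1L; i <- i - 1L
    } else {
      gaps <- gaps + 1L; j <- j - 1L
    }
    len <- len + 1L
  }
  list(score = F[n + 1, m + 1], pct = 100 * (mism + gaps) / len)
}

# longest common substring length by enumeration: intersect the sets of
# all substrings, longest length first
lcs_oracle <- function(a, b) {
  n <- nchar(a); m <- nchar(b)
  for (L in seq(min(n, m), 1)) {
    sa <- unique(substring(a, 1:(n - L + 1), L:n))
    sb <- unique(substring(b, 1:(m - L + 1), L:m))
    if (length(intersect(sa, sb)) > 0) return(L)
  }
  0L
}

# maximal substrings common to all strings, length >= min_len: brute
# force over every substring of the shortest string
motif_oracle <- function(ncrs, min_len) {
  pivot <- ncrs[[which.min(nchar(ncrs))]]
  n <- nchar(pivot)
  common <- character()
  for (L in seq(n, min_len)) {
    subs <- unique(substring(pivot, 1:(n - L + 1), L:n))
    ok <- subs[vapply(subs, function(s) {
      all(vapply(ncrs, grepl, logical(1), pattern = s, fixed = TRUE))
    }, logical(1))]
    ok <- ok[!vapply(ok, function(s) {
      any(vapply(common, grepl, logical(1), pattern = s, fixed = TRUE))
    }, logical(1))]
    common <- c(common, ok)
  }
  sort(common)
}

# exhaustive maximum total-overlap matching between two karyotypes
# (injective, partial allowed); returns the optimal total overlap
matching_oracle <- function(k1, k2) {
  c1 <- k1$minichromosomes; c2 <- k2$minichromosomes
  ov <- outer(seq_along(c1), seq_along(c2),
              Vectorize(function(i, j) {
                length(intersect(
                  unique(c1[[i]]$genes$name[c1[[i]]$genes$status == "full"]),
                  unique(c2[[j]]$genes$name[c2[[j]]$genes$status == "full"])))
              }))
  n1 <- length(c1); n2 <- length(c2)
  best <- 0
  assign_next <- function(i, used, total) {
    if (i > n1) { best <<- max(best, total); return(invisible()) }
    assign_next(i + 1, used, total)  # leave i unmatched
    for (j in setdiff(seq_len(n2), used)) {
      if (ov[i, j] > 0) assign_next(i + 1, c(used, j), total + ov[i, j])
    }
  }
  assign_next(1, integer(), 0)
  best
}

# random karyotype grammar documents for round-trip testing: random
# orientation, pseudo and duplicate-tag decoration, optional size
# columns
random_karyotype_text <- function(n_chrom = NULL) {
  vocab <- canonical_vocabulary()$name
  if (is.null(n_chrom)) n_chrom <- sample(2:6, 1)
  genes <- sample(vocab, sample(seq(2 * n_chrom, min(20, 37)), 1))
  sizes <- rep(2L, n_chrom)
  extra <- length(genes) - 2L * n_chrom
  if (extra > 0) {
    add <- table(factor(sample(seq_len(n_chrom), extra, replace = TRUE),
                        levels = seq_len(n_chrom)))
    sizes <- sizes + as.integer(add)
  }
  ends <- cumsum(sizes); starts <- c(1L, head(ends, -1) + 1L)
  lines <- vapply(seq_len(n_chrom), function(i) {
    nm <- genes[starts[i]:ends[i]]
    tok <- vapply(nm, function(g) {
      t <- g
      if (runif(1) < 0.15) t <- paste0("p", t)
      if (runif(1) < 0.10) t <- paste0(t, "#", sample(2:3, 1))
      if (runif(1) < 0.15) t <- paste0("~", t)
      t
    }, character(1))
    line <- paste(tok, collapse = "-")
    if (runif(1) < 0.5) {
      line <- paste(c(line, sample(500:3000, 4)), collapse = "\t")
    }
    line
  }, character(1))
  paste(lines, collapse = "\n")
}

# toy-scale synthetic genome + reads used by assembler tests
toy_genome <- function(seed, ncr_divergence = 0) {
  generate_ancestral_genome(
    gene_lengths = default_gene_lengths("toy"),
    ncr_len = c(250L, 400L),
    motif_spec = default_motif_spec(at_len = 30L, gc_len = 30L),
    ncr_divergence = ncr_divergence,
    seed = seed)
}

toy_reads <- function(genome, seed, coverage = 30, error_rate = 0) {
  simulate_reads(genome, coverage = coverage, read_len = 150L,
                 insert_len = 300L, error_rate = error_rate, seed = seed)
}

gene_seq <- function(genome, chrom, gene) {
  m <- genome$karyotype$minichromosomes[[chrom]]
  m$genes$sequence[m$genes$name == gene & m$genes$status == "full"][1]
}

# run the full filter -> seed x2 -> consensus -> bait pipeline on a toy
# genome; returns list(circles, contigs)
toy_assembly <- function(seed) {
  g <- toy_genome(seed)
  reads <- filter_reads(toy_reads(g, seed + 1000L))
  c1 <- iterative_extend(reads, gene_seq(g, "K-nad4", "nad4"),
                         min_overlap = 60L)
  c2 <- iterative_extend(reads, gene_seq(g, "I-cox1", "cox1"),
                         min_overlap = 60L)
  cons <- derive_ncr_consensus(c1, c2, min_overlap = 60L)
  contigs <- bait_assemble(reads, cons, min_overlap = 60L,
                           flank_len = 25L)
  list(circles = genome_circles(g), contigs = contigs)
}
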