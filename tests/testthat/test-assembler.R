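test_that("the read filter enforces both rules and is idempotent", {
  g <- toy_genome(21)
  clean <- toy_reads(g, 22)[1:30, ]
  expect_equal(nrow(filter_reads(clean)), 30L)  # Q37, no N: all retained

  # a mate with 11% N knocks out the pair; 9% passes
  dirty <- clean
  n11 <- ceiling(0.11 * 150)
  substr(dirty$read2[3], 1, n11) <- strrep("N", n11)
  n9 <- floor(0.09 * 150)
  substr(dirty$read1[5], 1, n9) <- strrep("N", n9)
  kept <- filter_reads(dirty)
  expect_false(dirty$id[3] %in% kept$id)
  expect_true(dirty$id[5] %in% kept$id)

  # 51% low-quality bases on one mate drops the pair
  lowq <- clean
  nl <- ceiling(0.51 * 150)
  substr(lowq$qual1[7], 1, nl) <- strrep("#", nl)  # Q2
  expect_false(lowq$id[7] %in% filter_reads(lowq)$id)

  # randomized fixtures against a per-record brute-force evaluation
  set.seed(55)
  rnd <- clean
  for (i in seq_len(nrow(rnd))) {
    kN <- sample(0:25, 1)
    if (kN > 0) substr(rnd$read1[i], 1, kN) <- strrep("N", kN)
    kQ <- sample(0:100, 1)
    if (kQ > 0) substr(rnd$qual2[i], 1, kQ) <- strrep("5", kQ)  # Q20
  }
  brute <- vapply(seq_len(nrow(rnd)), function(i) {
    ok <- function(s, q) {
      nfrac <- sum(strsplit(s, "")[[1]] == "N") / nchar(s)
      lfrac <- sum(utf8ToInt(q) - 33 <= 20) / nchar(q)
      nfrac <= 0.10 && lfrac <= 0.50
    }
    ok(rnd$read1[i], rnd$qual1[i]) && ok(rnd$read2[i], rnd$qual2[i])
  }, logical(1))
  expect_identical(filter_reads(rnd)$id, rnd$id[brute])

  # idempotence
  once <- filter_reads(rnd)
  expect_identical(filter_reads(once), once)
})

test_that("a full-scale circle assembles exactly under the default
           protocol parameters", {
  # one ~2.7 kb minichromosome (cox1 analogue seed), 300 bp reads,
  # 530 bp inserts, minimum overlap 200 bp at 99% identity
  g <- generate_ancestral_genome(seed = 61)
  circles <- genome_circles(g)
  reads <- simulate_reads(g, coverage = 30, seed = 62)
  own <- reads[reads$chrom == "I-cox1", ]
  ctg <- iterative_extend(own, gene_seq(g, "I-cox1", "cox1"))
  expect_true(ctg$circular)
  expect_true(rotation_equivalent(ctg$sequence, circles[["I-cox1"]]))
  expect_equal(nchar(ctg$sequence), nchar(circles[["I-cox1"]]))

  # reads from a different minichromosome only: seed is not covered
  other <- reads[reads$chrom == "K-nad4", ]
  expect_error(iterative_extend(other, gene_seq(g, "I-cox1", "cox1")),
               "seed not covered")
})

test_that("substitution errors are absorbed by the consensus", {
  g <- toy_genome(71)
  circles <- genome_circles(g)
  reads <- toy_reads(g, 72, coverage = 50, error_rate = 0.01)
  own <- reads[reads$chrom == "K-nad4", ]
  ctg <- iterative_extend(own, gene_seq(g, "K-nad4", "nad4"),
                          min_overlap = 60L, min_identity = 0.95)
  expect_true(ctg$circular)
  truth <- circles[["K-nad4"]]
  expect_equal(nchar(ctg$sequence), nchar(truth))
  # align by rotation via a long exact anchor, then compare
  d2 <- paste0(truth, truth)
  anchor <- longest_shared_stretch(ctg$sequence, d2)
  shift <- ((anchor$pos_b - anchor$pos_a) %% nchar(truth)) + 1L
  rotated <- substr(d2, shift, shift + nchar(truth) - 1L)
  expect_lt(as.numeric(percent_difference(ctg$sequence, rotated)), 0.5)
})

test_that("raising the identity threshold never accepts more overlaps", {
  g <- toy_genome(81)
  reads <- toy_reads(g, 82)
  seed <- gene_seq(g, "K-nad4", "nad4")
  # plant one mismatch inside every copy of the seed region in the reads
  mutated <- reads
  pos <- 30L
  target <- substr(seed, pos, pos + 59L)
  # at 100% identity the mutated window is rejected; at 95% accepted
  mut_window <- target
  substr(mut_window, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                        substr(target, 30, 30))[1]
  fake_reads <- vapply(1:40, function(i) {
    paste0(minikaryo:::random_seq(40, 0.3), mut_window,
           minikaryo:::random_seq(40, 0.3))
  }, character(1))
  expect_error(iterative_extend(fake_reads, target, min_overlap = 60L,
                                min_identity = 1.0), "seed not covered")
  ctg <- iterative_extend(fake_reads, target, min_overlap = 60L,
                          min_identity = 0.95)
  expect_s3_class(ctg, "contig")
})

test_that("the NCR consensus is recovered between two seed circles", {
  g <- toy_genome(91)
  reads <- filter_reads(toy_reads(g, 92))
  c1 <- iterative_extend(reads, gene_seq(g, "K-nad4", "nad4"),
                         min_overlap = 60L)
  c2 <- iterative_extend(reads, gene_seq(g, "I-cox1", "cox1"),
                         min_overlap = 60L)
  expect_true(c1$circular && c2$circular)
  cons <- derive_ncr_consensus(c1, c2, min_overlap = 60L)
  ncr <- g$karyotype$minichromosomes[[1]]$ncr_sequence
  expect_gte(attr(cons, "length"), nchar(ncr) - 2L * 8L - 4L)
  expect_true(grepl(substr(cons, 10, nchar(cons) - 10), paste0(ncr, ncr),
                    fixed = TRUE))

  # identical contigs share (nearly) the whole circle
  whole <- derive_ncr_consensus(c1, c1, min_overlap = 60L)
  expect_gte(attr(whole, "length"), nchar(c1$sequence) - 2L * 8L - 2L)

  # two circles whose NCRs differ by 2 substitutions still yield a
  # consensus covering (nearly) the whole NCR
  ncr_b <- ncr
  substr(ncr_b, 100, 100) <- "A"; substr(ncr_b, 200, 200) <- "T"
  circ_a <- paste0(minikaryo:::random_seq(400, 0.3), ncr)
  circ_b <- paste0(minikaryo:::random_seq(400, 0.3), ncr_b)
  cons2 <- derive_ncr_consensus(
    structure(list(sequence = circ_a, circular = TRUE), class = "contig"),
    structure(list(sequence = circ_b, circular = TRUE), class = "contig"),
    min_overlap = 60L, min_identity = 0.95)
  expect_gte(attr(cons2, "length"), nchar(ncr) - 2L * 8L - 10L)
  # consensus bases come from contig_a, whose NCR is the truth NCR
  expect_true(grepl(as.character(cons2), paste0(ncr, ncr), fixed = TRUE))
  expect_error(derive_ncr_consensus(
    structure(list(sequence = circ_a, circular = FALSE),
              class = "contig"), c1), "not circular")
})

test_that("NCR bait recovers one contig from single-minichromosome reads", {
  g <- toy_genome(95)
  reads <- toy_reads(g, 96)
  own <- reads[reads$chrom == "K-nad4", ]
  ncr <- g$karyotype$minichromosomes[["K-nad4"]]$ncr_sequence
  ctgs <- bait_assemble(own, ncr, min_overlap = 60L, flank_len = 25L)
  expect_equal(attr(ctgs, "n_minichromosomes"), 1L)
  expect_true(rotation_equivalent(ctgs[[1]]$sequence,
                                  genome_circles(g)[["K-nad4"]]))
})

test_that("the full pipeline reconstructs a 10-minichromosome genome", {
  res <- toy_assembly(301)
  expect_equal(attr(res$contigs, "n_minichromosomes"),
               length(res$circles))
  hits <- vapply(res$contigs, function(ct) {
    which(vapply(res$circles, rotation_equivalent, logical(1),
                 a = ct$sequence))[1]
  }, integer(1))
  expect_false(anyNA(hits))
  expect_equal(sort(unique(hits)), seq_along(res$circles))
})

test_that("contig FASTA canonicalizes rotations deterministically", {
  res <- toy_assembly(302)
  fa <- tempfile(fileext = ".fasta")
  rep <- tempfile(fileext = ".json")
  write_contigs(res$contigs, fa, report_path = rep)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(seqs), length(res$contigs))
  js <- jsonlite::fromJSON(rep)
  expect_equal(nrow(js), length(res$contigs))
  expect_true(all(js$circular))
})
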