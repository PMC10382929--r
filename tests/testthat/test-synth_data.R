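test_that("the generator is deterministic and plants both motifs", {
  g1 <- generate_ancestral_genome(seed = 42)
  g2 <- generate_ancestral_genome(seed = 42)
  expect_identical(genome_circles(g1), genome_circles(g2))
  g3 <- generate_ancestral_genome(seed = 43)
  expect_false(identical(genome_circles(g1), genome_circles(g3)))

  for (m in g1$karyotype$minichromosomes) {
    expect_true(grepl(g1$motifs$sequence[1], m$ncr_sequence, fixed = TRUE))
    expect_true(grepl(g1$motifs$sequence[2], m$ncr_sequence, fixed = TRUE))
  }
  expect_equal(minikaryo:::at_fraction(g1$motifs$sequence[1]), 1.0)
})

test_that("generated karyotypes respect the model invariants", {
  g <- generate_ancestral_genome(seed = 3)
  k <- g$karyotype
  expect_equal(length(k$minichromosomes), 10L)
  s <- summarize_karyotype(k)
  expect_equal(s$n_distinct_full_genes, 37L)
  expect_equal(s$n_duplicate_genes, 0L)
  expect_true(s$genes_per_chrom_min >= 2 && s$genes_per_chrom_max <= 8)
  for (m in k$minichromosomes) {
    # size additivity holds for synthetic genomes
    expect_equal(m$total_len_bp, m$cluster_len_bp + m$ncr_len_bp)
    expect_equal(nchar(m$cluster_sequence), m$cluster_len_bp)
    expect_equal(nchar(m$ncr_sequence), m$ncr_len_bp)
  }
  # round-trips through the grammar like any karyotype
  expect_identical(
    serialize_karyotype(parse_karyotype(serialize_karyotype(k))),
    serialize_karyotype(k))
})

test_that("motif recovery closes the loop on divergent NCR backgrounds", {
  g <- generate_ancestral_genome(seed = 42, ncr_divergence = 0.1)
  ncrs <- vapply(g$karyotype$minichromosomes, `[[`, character(1),
                 "ncr_sequence")
  hits <- find_conserved_motifs(ncrs, min_len = 20)
  expect_true(any(grepl(g$motifs$sequence[1], hits$consensus,
                        fixed = TRUE)))
  expect_true(any(grepl(g$motifs$sequence[2], hits$consensus,
                        fixed = TRUE)))
  up <- hits[grepl(g$motifs$sequence[1], hits$consensus, fixed = TRUE), ]
  dn <- hits[grepl(g$motifs$sequence[2], hits$consensus, fixed = TRUE), ]
  expect_equal(up$position_class[1], "upstream_of_cluster")
  expect_equal(dn$position_class[1], "downstream_of_cluster")
})

test_that("bad partitions are rejected", {
  part <- default_gene_partition()
  expect_error(generate_ancestral_genome(partition = part[-1]),
               "partition size")
  part2 <- part
  part2[3] <- "I-cox1-W"  # W now twice
  expect_error(generate_ancestral_genome(partition = part2),
               "exactly once")
  part3 <- part
  part3[3] <- "I-pcox1"
  expect_error(generate_ancestral_genome(partition = part3), "pseudo")
})

test_that("an explicit duplication makes sequence-identical copies", {
  g <- generate_ancestral_genome(seed = 8)
  ev <- data.frame(type = "duplication_insert", gene = "L1",
                   donor = "M-L1-rrnL-V", recipient = "D-nad2",
                   recipient_ancestral = "D-nad2",
                   location_anchor = NA, n_genes = 1L,
                   insert_pos = 2L, window_start = NA, window_len = NA)
  out <- apply_events(g, events = ev)
  k <- out$genome$karyotype
  occ <- gene_index(k)
  l1 <- occ[occ$name == "L1" & occ$status == "full", ]
  expect_equal(nrow(l1), 2L)
  seqs <- vapply(seq_len(nrow(l1)), function(i) {
    k$minichromosomes[[l1$chrom[i]]]$genes$sequence[l1$position[i]]
  }, character(1))
  expect_identical(seqs[1], seqs[2])  # copies identical in sequence
  # inserted upstream of nad2 on the recipient
  expect_true("D-L1#2-nad2" %in% names(k$minichromosomes))
})

test_that("empty event lists change nothing and logs replay exactly", {
  g <- generate_ancestral_genome(seed = 10)
  out <- apply_events(g, events = minikaryo:::empty_truth_events())
  expect_identical(genome_circles(out$genome), genome_circles(g))
  expect_equal(nrow(out$truth$events), 0L)

  for (s in 1:5) {
    ae <- apply_events(g, n_events = 3L, seed = s)
    replay <- apply_events(g, events = ae$truth$events)
    expect_identical(serialize_karyotype(replay$genome$karyotype),
                     serialize_karyotype(ae$genome$karyotype))
    expect_identical(genome_circles(replay$genome),
                     genome_circles(ae$genome))
  }
})

test_that("inapplicable events fail loudly", {
  g <- generate_ancestral_genome(seed = 10)
  bad <- data.frame(type = "translocation", gene = "W",
                    donor = "K-nad4", recipient = "I-cox1",
                    recipient_ancestral = "I-cox1",
                    location_anchor = NA, n_genes = 1L, insert_pos = 1L,
                    window_start = NA, window_len = NA)
  expect_error(apply_events(g, events = bad), "inapplicable")
})

test_that("random multi-event runs are recovered by inference", {
  g <- generate_ancestral_genome(attach_sequences = FALSE, seed = 77)
  ok <- vapply(1:20, function(s) {
    ae <- apply_events(g, n_events = sample(1:3, 1), seed = 300L + s)
    events_match(ae$truth, infer_events(g$karyotype,
                                        ae$genome$karyotype))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("read simulation honours coverage, origin and determinism", {
  g <- toy_genome(2)
  reads <- toy_reads(g, 5, coverage = 30)
  circles <- genome_circles(g)
  for (lab in names(circles)) {
    sub <- reads[reads$chrom == lab, ]
    L <- nchar(circles[[lab]])
    # closed-form pair count, within one pair
    expect_lte(abs(nrow(sub) - 30 * L / (2 * 150)), 1)
    # mean per-base depth within 15% of the target
    depth <- nrow(sub) * 2 * 150 / L
    expect_lt(abs(depth - 30) / 30, 0.15)
    # error-free reads are exact substrings of their origin circle
    doubled <- paste0(circles[[lab]], circles[[lab]])
    for (i in seq_len(min(10, nrow(sub)))) {
      expect_true(grepl(sub$read1[i], doubled, fixed = TRUE) ||
                    grepl(revcomp(sub$read1[i]), doubled, fixed = TRUE))
      expect_true(grepl(sub$read2[i], doubled, fixed = TRUE) ||
                    grepl(revcomp(sub$read2[i]), doubled, fixed = TRUE))
    }
  }
  expect_identical(reads, toy_reads(g, 5, coverage = 30))
  expect_error(simulate_reads(g, coverage = 30, read_len = 150,
                              insert_len = 10000), "insert_len")
  expect_error(simulate_reads(g, coverage = 30, read_len = 300,
                              insert_len = 200), "insert_len")
})

test_that("FASTQ output round-trips and malformed input is located", {
  g <- toy_genome(3)
  reads <- toy_reads(g, 6)[1:20, ]
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(reads, f1, f2)
  back <- read_fastq_pairs(f1, f2)
  expect_equal(back$read1, reads$read1)
  expect_equal(back$read2, reads$read2)
  expect_equal(back$qual1, reads$qual1)

  lines <- readLines(f1)
  lines[5] <- "not_a_header"
  f3 <- tempfile(fileext = ".fastq")
  writeLines(lines, f3)
  expect_error(read_fastq_pairs(f3, f2), "record 2")
  writeLines(lines[1:6], f3)
  expect_error(read_fastq_pairs(f3, f2), "multiple of 4")
})
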