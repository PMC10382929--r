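test_that("canonical vocabulary has the standard 37-gene composition", {
  v <- canonical_vocabulary()
  expect_equal(nrow(v), 37L)
  expect_equal(sum(v$kind == "PCG"), 13L)
  expect_equal(sum(v$kind == "tRNA"), 22L)
  expect_equal(sum(v$kind == "rRNA"), 2L)
  expect_equal(anyDuplicated(v$name), 0L)
})

test_that("the grammar parses tokens, orientations and decorations", {
  k <- parse_karyotype("I-cox1")
  expect_equal(length(k$minichromosomes), 1L)
  g <- k$minichromosomes[[1]]$genes
  expect_equal(g$name, c("I", "cox1"))
  expect_equal(g$kind, c("tRNA", "PCG"))
  expect_true(all(g$orientation == "forward"))
  expect_true(all(g$status == "full"))

  k2 <- parse_karyotype("~Q-~nad1-~T-G-nad3")
  g2 <- k2$minichromosomes[[1]]$genes
  expect_equal(nrow(g2), 5L)
  expect_equal(g2$orientation,
               c("reverse", "reverse", "reverse", "forward", "forward"))

  k3 <- parse_karyotype("prrnS#2-pcox2-D-L1#2-nad2")
  g3 <- k3$minichromosomes[[1]]$genes
  expect_equal(g3$status, c("pseudo", "pseudo", "full", "full", "full"))
  expect_equal(g3$copy, c(2L, NA, NA, 2L, NA))
})

test_that("parse errors name the line and token", {
  expect_error(parse_karyotype("I-cox9"), "line 1.*cox9")
  expect_error(parse_karyotype("I-cox1\nI-cox1"), "duplicate")
  expect_error(parse_karyotype("  \n# only comments"), "empty")
  expect_error(parse_karyotype("I-cox1\tabc"), "non-numeric")
})

test_that("fixtures round-trip byte-identically", {
  for (name in c("L_vituli", "L_africanus", "MRCA_Anoplura",
                 "MRCA_Linognathus")) {
    path <- system.file("extdata", paste0(name, ".txt"),
                        package = "minikaryo")
    raw <- readLines(path)
    raw <- raw[nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")]
    k <- load_fixture(name)
    expect_identical(serialize_karyotype(k), paste(raw, collapse = "\n"),
                     label = name)
  }
})

test_that("serialize-parse round-trips on 1,000 random karyotypes", {
  set.seed(101)
  for (i in 1:1000) {
    txt <- random_karyotype_text()
    k <- parse_karyotype(txt)
    expect_identical(serialize_karyotype(k), txt)
    expect_identical(serialize_karyotype(parse_karyotype(
      serialize_karyotype(k))), txt)
  }
})

test_that("karyotype JSON round-trips", {
  k <- load_fixture("L_africanus")
  k2 <- karyotype_from_json(karyotype_to_json(k))
  expect_identical(serialize_karyotype(k2), serialize_karyotype(k))
  expect_identical(k2$species, k$species)
})

test_that("summaries reproduce the published per-species roll-ups", {
  sv <- summarize_karyotype(load_fixture("L_vituli"))
  expect_equal(sv$n_minichromosomes, 10L)
  expect_equal(sv$n_distinct_full_genes, 37L)
  expect_equal(sv$n_duplicate_genes, 1L)   # the second trnL1
  expect_equal(sv$n_pseudo_genes, 4L)
  expect_equal(sv$total_len_bp, 26258L)
  expect_equal(sv$cluster_len_bp, 14013L)
  expect_equal(sv$ncr_len_bp, 11210L)
  expect_equal(sv$pseudo_len_bp, 851L)
  expect_equal(c(sv$genes_per_chrom_min, sv$genes_per_chrom_max),
               c(2L, 8L))

  sa <- summarize_karyotype(load_fixture("L_africanus"))
  expect_equal(sa$n_minichromosomes, 10L)
  expect_equal(sa$n_duplicate_genes, 3L)   # trnL1, trnH, trnM
  expect_equal(sa$n_pseudo_genes, 1L)      # patp8
  expect_equal(sa$total_len_bp, 35270L)
  expect_equal(sa$pseudo_len_bp, 170L)
})

test_that("summary totals equal independent column sums of the table", {
  for (name in c("L_vituli", "L_africanus")) {
    path <- system.file("extdata", paste0(name, ".txt"),
                        package = "minikaryo")
    # independent brute-force re-read of the size columns ("#" also
    # appears inside duplicate tags, so split lines by hand)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    cells <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    tab <- data.frame(V2 = as.integer(cells[, 2]),
                      V3 = as.integer(cells[, 3]),
                      V4 = as.integer(cells[, 4]),
                      V5 = as.integer(cells[, 5]))
    s <- summarize_karyotype(load_fixture(name))
    expect_equal(s$total_len_bp, sum(tab$V2), label = name)
    expect_equal(s$cluster_len_bp, sum(tab$V3), label = name)
    expect_equal(s$ncr_len_bp, sum(tab$V4), label = name)
    expect_equal(s$pseudo_len_bp, sum(tab$V5), label = name)
    counts <- vapply(load_fixture(name)$minichromosomes,
                     function(m) sum(m$genes$status == "full"), integer(1))
    expect_true(all(counts >= 2 & counts <= 8), label = name)
  }
})

test_that("minimal karyotypes summarize sensibly and sizes stay absent", {
  s <- summarize_karyotype(parse_karyotype("I-cox1"))
  expect_equal(s$n_minichromosomes, 1L)
  expect_equal(s$n_distinct_full_genes, 2L)
  expect_equal(s$n_duplicate_genes, 0L)
  expect_equal(s$n_pseudo_genes, 0L)
  expect_true(is.na(s$total_len_bp))  # absent, never zero
})

test_that("fixture loader validates names and ancestral content", {
  expect_error(load_fixture("nope"), "unknown fixture")
  anc <- load_fixture("MRCA_Anoplura")
  expect_equal(length(anc$minichromosomes), 11L)
  expect_true("K-nad4" %in% names(anc$minichromosomes))
  expect_true("rrnS-C" %in% names(anc$minichromosomes))
  expect_true("atp8-atp6-N" %in% names(anc$minichromosomes))
  expect_true("nad2" %in% names(anc$minichromosomes))
  ix <- gene_index(anc)
  # rrnS, rrnL and trnH sit on three different minichromosomes
  expect_equal(length(unique(ix$chrom[ix$name %in%
                                        c("rrnS", "rrnL", "H")])), 3L)
  # trnD and cox2 share a minichromosome
  expect_equal(ix$chrom[ix$name == "D"], ix$chrom[ix$name == "cox2"])
  expect_equal(length(load_fixture("MRCA_Linognathus")$minichromosomes),
               10L)
})
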