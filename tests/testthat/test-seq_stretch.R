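test_that("percent difference handles the basic identities", {
  expect_equal(as.numeric(percent_difference("ACGTACGT", "ACGTACGT")), 0)
  expect_equal(as.numeric(percent_difference("ACGT", "ACGA")), 25)
  a <- minikaryo:::random_seq(80, 0.4); b <- minikaryo:::random_seq(75, 0.4)
  expect_equal(as.numeric(percent_difference(a, b)),
               as.numeric(percent_difference(b, a)))
  expect_error(percent_difference("", "ACGT"), "non-empty")
  expect_error(percent_difference("ACGT", "ACXT"), "outside")
})

test_that("percent difference agrees with a full-DP oracle", {
  set.seed(21)
  for (i in 1:10) {
    a <- minikaryo:::random_seq(60, 0.35)
    # plant 3 substitutions and 1 deletion
    chars <- strsplit(a, "")[[1]]
    for (p in sample(60, 3)) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    b <- paste(chars[-sample(60, 1)], collapse = "")
    got <- percent_difference(a, b)
    ora <- nw_oracle(a, b)
    expect_equal(as.numeric(got), ora$pct, tolerance = 1e-8)
  }
})

test_that("longest shared stretch finds planted and degenerate cases", {
  hit <- longest_shared_stretch("AAAA", "CCCC")
  expect_equal(hit$length_bp, 0L)

  set.seed(4)
  core <- minikaryo:::random_seq(50, 0.5)
  a <- paste0(minikaryo:::random_seq(200, 0.5), core,
              minikaryo:::random_seq(250, 0.5))
  b <- paste0(minikaryo:::random_seq(100, 0.5), core,
              minikaryo:::random_seq(350, 0.5))
  hit <- longest_shared_stretch(a, b)
  expect_gte(hit$length_bp, 50L)
  expect_identical(substr(a, hit$pos_a, hit$pos_a + hit$length_bp - 1L),
                   substr(b, hit$pos_b, hit$pos_b + hit$length_bp - 1L))
})

test_that("longest shared stretch equals the enumeration oracle", {
  set.seed(17)
  for (i in 1:30) {
    a <- minikaryo:::random_seq(120, 0.5)
    b <- minikaryo:::random_seq(150, 0.5)
    hit <- longest_shared_stretch(a, b)
    expect_equal(hit$length_bp, lcs_oracle(a, b))
    expect_equal(longest_shared_stretch(b, a)$length_bp, hit$length_bp)
  }
})

test_that("reverse-complement search reports mapped coordinates", {
  set.seed(5)
  core <- minikaryo:::random_seq(40, 0.5)
  a <- paste0(minikaryo:::random_seq(60, 0.5), core,
              minikaryo:::random_seq(60, 0.5))
  b <- paste0(minikaryo:::random_seq(30, 0.5), revcomp(core),
              minikaryo:::random_seq(30, 0.5))
  hit <- longest_shared_stretch(a, b, include_revcomp = TRUE)
  expect_equal(hit$strand, "revcomp")
  expect_gte(hit$length_bp, 40L)
  sub_a <- substr(a, hit$pos_a, hit$pos_a + hit$length_bp - 1L)
  sub_b <- substr(b, hit$pos_b, hit$pos_b + hit$length_bp - 1L)
  expect_identical(sub_a, revcomp(sub_b))
})

test_that("the chance null is bounded, monotone and reproducible", {
  q <- stretch_null_quantile(200, 200, gc = 0.5, reps = 200, q = 0.99,
                             seed = 1)
  expect_lt(q, 200)
  expect_gte(q, 1)
  q_small <- stretch_null_quantile(100, 100, gc = 0.5, reps = 200,
                                   q = 0.5, seed = 7)
  q_large <- stretch_null_quantile(400, 100, gc = 0.5, reps = 200,
                                   q = 0.5, seed = 7)
  expect_lte(q_small, q_large)
  expect_identical(q_small,
                   stretch_null_quantile(100, 100, gc = 0.5, reps = 200,
                                         q = 0.5, seed = 7))
  expect_error(stretch_null_quantile(100, 100, gc = 2, reps = 200),
               "gc")
  expect_error(stretch_null_quantile(100, 100, reps = 10), "reps")
})

test_that("conserved motif discovery recovers planted motifs", {
  set.seed(31)
  motif <- paste(sample(c("A", "T"), 45, replace = TRUE), collapse = "")
  ncrs <- vapply(1:10, function(i) {
    left <- minikaryo:::random_seq(sample(100:180, 1), 0.5)
    right <- minikaryo:::random_seq(sample(20:60, 1), 0.5)
    paste0(left, motif, right)
  }, character(1))
  hits <- find_conserved_motifs(ncrs, min_len = 20)
  expect_gte(nrow(hits), 1L)
  top <- hits[1, ]
  expect_gte(top$length_bp, 45L)
  expect_true(grepl(motif, top$consensus, fixed = TRUE))
  expect_gte(top$AT_fraction, 0.9)
  # planted in the second (cluster-proximal) half: upstream class
  expect_equal(top$position_class, "upstream_of_cluster")
  # offsets point at real occurrences
  for (i in seq_along(ncrs)) {
    off <- hits$offsets[[1]][i]
    expect_identical(substr(ncrs[i], off, off + top$length_bp - 1L),
                     top$consensus)
  }
})

test_that("identical NCRs share their full length; disjoint share none", {
  ncr <- minikaryo:::random_seq(300, 0.4)
  hits <- find_conserved_motifs(rep(ncr, 4), min_len = 20)
  expect_equal(hits$length_bp[1], 300L)
  none <- find_conserved_motifs(c(strrep("A", 50), strrep("C", 50)),
                                min_len = 5)
  expect_equal(nrow(none), 0L)
  expect_error(find_conserved_motifs("ACGT"), "at least two")
})

test_that("motif discovery equals the brute-force oracle", {
  set.seed(41)
  for (i in 1:10) {
    motif <- minikaryo:::random_seq(30, 0.5)
    ncrs <- vapply(1:3, function(j) {
      paste0(minikaryo:::random_seq(sample(60:120, 1), 0.5), motif,
             minikaryo:::random_seq(sample(60:120, 1), 0.5))
    }, character(1))
    hits <- find_conserved_motifs(ncrs, min_len = 10)
    expect_identical(sort(hits$consensus), motif_oracle(ncrs, 10))
  }
})

test_that("motif AT fraction complements GC content", {
  s <- "AATTGGCC"
  expect_equal(minikaryo:::at_fraction(s), 0.5)
})
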