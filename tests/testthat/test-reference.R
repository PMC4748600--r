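toy <- toy_dna(2L, -1L)

test_that("empty-operand scores follow the gap function per class", {
  expect_equal(align_reference("sw", "", "ACGT", 2, 1, toy)$score, 0)
  expect_equal(align_reference("sg", "", "ACGT", 2, 1, toy)$score, 0)
  expect_equal(align_reference("nw", "", "AAA", 2, 1, toy)$score, -5)
  expect_equal(align_reference("nw", "AAA", "", 2, 1, toy)$score, -5)
  expect_equal(align_reference("nw", "", "", 2, 1, toy)$score, 0)
  r <- align_reference("sw", "", "ACGT", 2, 1, toy)
  expect_equal(c(r$end_query, r$end_ref), c(-1L, -1L))
})

test_that("small global and semi-global scores match the enumeration oracle", {
  # frozen from enum_global("AC","AGC",2,1,toy): A.A match + gap + C.C match
  expect_equal(enum_global("AC", "AGC", 2, 1, toy), 1)
  expect_equal(align_reference("nw", "AC", "AGC", 2, 1, toy)$score, 1)
  # frozen from enum_semiglobal("CC","ACCA",2,1,toy): free end gaps flank CC/CC
  expect_equal(enum_semiglobal("CC", "ACCA", 2, 1, toy), 4)
  expect_equal(align_reference("sg", "CC", "ACCA", 2, 1, toy)$score, 4)
})

test_that("randomized tiny instances match enumeration for all classes", {
  set.seed(101)
  for (rep in 1:25) {
    q <- rand_residues(sample(0:5, 1), c("A", "C", "G", "T"))
    d <- rand_residues(sample(0:5, 1), c("A", "C", "G", "T"))
    open <- sample(0:3, 1)
    ext <- sample(1:2, 1)
    expect_equal(align_reference("nw", q, d, open, ext, toy)$score,
      enum_global(q, d, open, ext, toy),
      info = sprintf("nw %s/%s o%d e%d", q, d, open, ext))
    expect_equal(align_reference("sg", q, d, open, ext, toy)$score,
      enum_semiglobal(q, d, open, ext, toy),
      info = sprintf("sg %s/%s", q, d))
    expect_equal(align_reference("sw", q, d, open, ext, toy)$score,
      enum_local(q, d, open, ext, toy),
      info = sprintf("sw %s/%s", q, d))
  }
})

test_that("protein scores agree with the Biostrings implementation", {
  b62 <- builtin_matrix("BLOSUM62")
  pam <- builtin_matrix("PAM250")
  set.seed(7)
  for (rep in 1:30) {
    q <- rand_residues(sample(1:40, 1), aa20)
    d <- rand_residues(sample(1:40, 1), aa20)
    mat <- if (rep %% 2) b62 else pam
    for (cls in c("nw", "sg", "sw")) {
      b <- bios_score(cls, q, d, 11, 1, mat)
      # Biostrings' overlap type admits the empty alignment (score floor 0);
      # semi-global here requires a non-empty alignment, so compare the two
      # only when the overlap optimum is positive and the conventions agree
      if (cls == "sg" && b <= 0) next
      expect_equal(align_reference(cls, q, d, 11, 1, mat)$score, b,
        info = sprintf("%s rep %d", cls, rep))
    }
  }
})

test_that("local alignment equals the best substring-pair global score", {
  set.seed(11)
  for (rep in 1:8) {
    q <- rand_residues(sample(1:8, 1), c("A", "C", "G", "T"))
    d <- rand_residues(sample(1:8, 1), c("A", "C", "G", "T"))
    expect_equal(align_reference("sw", q, d, 2, 1, toy)$score,
      enum_local(q, d, 2, 1, toy), info = paste(q, d))
  }
})

test_that("table variant has interior shape and the local clamp", {
  r <- align_reference("sw", "AC", "AGT", 2, 1, toy, want_table = TRUE)
  expect_equal(dim(r$table), c(2L, 3L))
  expect_true(all(r$table >= 0))
  r2 <- align_reference("nw", "AC", "AGT", 2, 1, toy,
    want_table = TRUE, want_rowcol = TRUE)
  expect_equal(r2$last_row, r2$table[2, ])
  expect_equal(r2$last_col, r2$table[, 3])
  expect_equal(r2$table[2, 3], as.integer(r2$score))
})

test_that("class relaxation, symmetry, and gap monotonicity hold on random corpora", {
  b62 <- builtin_matrix("BLOSUM62")
  set.seed(23)
  for (rep in 1:40) {
    q <- rand_residues(sample(0:60, 1), aa20)
    d <- rand_residues(sample(0:60, 1), aa20)
    s_nw <- align_reference("nw", q, d, 11, 1, b62)$score
    s_sg <- align_reference("sg", q, d, 11, 1, b62)$score
    s_sw <- align_reference("sw", q, d, 11, 1, b62)$score
    expect_gte(s_sw, s_sg)
    expect_gte(s_sg, s_nw)
    # symmetric matrix implies argument symmetry
    for (cls in c("nw", "sg", "sw")) {
      expect_equal(align_reference(cls, d, q, 11, 1, b62)$score,
        switch(cls, nw = s_nw, sg = s_sg, sw = s_sw), info = cls)
    }
    # raising either penalty never raises any score
    for (cls in c("nw", "sg", "sw")) {
      base <- align_reference(cls, q, d, 5, 1, b62)$score
      expect_lte(align_reference(cls, q, d, 8, 1, b62)$score, base)
      expect_lte(align_reference(cls, q, d, 5, 3, b62)$score, base)
    }
  }
})

test_that("global self-alignment under a dominant diagonal sums the diagonal", {
  b62 <- builtin_matrix("BLOSUM62") # every diagonal entry dominates its row/col
  set.seed(31)
  for (rep in 1:10) {
    s <- rand_residues(sample(1:80, 1), aa20)
    e <- encode_sequence(s, b62)
    expected <- sum(diag(b62$scores)[e$residues + 1L])
    expect_equal(align_reference("nw", s, s, 11, 1, b62)$score, expected)
  }
})

test_that("end positions follow the smallest-ref-then-query tie-break", {
  # two equally scoring local matches: "AC" at db positions 1-2 and 4-5
  r <- align_reference("sw", "AC", "ACTAC", 2, 1, toy)
  expect_equal(r$score, 4)
  expect_equal(c(r$end_query, r$end_ref), c(1L, 1L))
})

test_that("statistics count matches, similars, and gapped columns on the optimal path", {
  b62 <- builtin_matrix("BLOSUM62")
  r <- align_reference("nw", "HEAGAWGHEE", "HEAGAWGHEE", 11, 1, b62,
    want_stats = TRUE)
  expect_equal(r$stats$matches, 10)
  expect_equal(r$stats$length, 10)
  # a forced single gap: identical flanks around one extra residue
  r2 <- align_reference("nw", "ACGT", "ACGGT", 2, 1, toy, want_stats = TRUE)
  expect_equal(r2$stats$length, 5)
  expect_equal(r2$stats$matches, 4)
  # bounds: matches <= similar-along-path <= length, matches <= min(m, n)
  set.seed(41)
  for (rep in 1:20) {
    q <- rand_residues(sample(1:50, 1), aa20)
    d <- rand_residues(sample(1:50, 1), aa20)
    cls <- sample(c("nw", "sg", "sw"), 1)
    st <- align_reference(cls, q, d, 11, 1, b62, want_stats = TRUE)$stats
    expect_lte(st$matches, st$length)
    expect_lte(st$similar, st$length)
    expect_lte(st$matches, min(nchar(q), nchar(d)))
    expect_gte(st$length, 0)
  }
})

test_that("negative gap magnitudes are rejected", {
  expect_error(align_reference("nw", "AC", "AC", -2, 1, toy), "nonnegative")
})
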