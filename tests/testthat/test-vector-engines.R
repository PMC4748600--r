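toy <- toy_dna(2L, -1L)
toy5 <- toy_dna(5L, -2L)

engine_fn <- function(engine) {
  switch(engine, striped = align_striped, scan = align_scan, diag = align_diag)
}

same_result <- function(ref, res) {
  identical(ref$score, res$score) &&
    identical(ref$end_query, res$end_query) &&
    identical(ref$end_ref, res$end_ref) &&
    identical(ref$stats, res$stats) &&
    identical(ref$table, res$table) &&
    identical(ref$last_row, res$last_row) &&
    identical(ref$last_col, res$last_col)
}

test_that("striped profile implements the lane/segment mapping", {
  p <- build_profile("AC", toy, "striped", lane_config(16, 2), cls = "nw")
  expect_equal(p$segment_length, 1L)
  # t = 1: word 0 lane 0 = position 1 (A), lane 1 = position 2 (C)
  for (sym in c("A", "C", "G", "T")) {
    expect_equal(profile_score(p, sym, 1), toy$scores["A", sym])
    expect_equal(profile_score(p, sym, 2), toy$scores["C", sym])
  }
})

test_that("profile decoding equals direct matrix lookup at every position", {
  b62 <- builtin_matrix("BLOSUM62")
  set.seed(5)
  q <- rand_residues(23, aa20)
  qc <- strsplit(q, "")[[1]]
  for (lanes in c(2, 4, 8)) {
    p <- build_profile(q, b62, "striped", lane_config(16, lanes), cls = "sw")
    for (pos in seq_len(nchar(q))) {
      for (sym in c("A", "W", "C")) {
        expect_equal(profile_score(p, sym, pos), b62$scores[qc[pos], sym],
          info = sprintf("lanes %d pos %d sym %s", lanes, pos, sym))
      }
    }
  }
})

test_that("padded profiles leave the optimum unchanged", {
  # query length 5 with 4 lanes: t = 2, three padding slots
  b62 <- builtin_matrix("BLOSUM62")
  p <- build_profile("MKVTW", b62, "striped", lane_config(16, 4), cls = "sw")
  expect_equal(p$segment_length, 2L)
  set.seed(9)
  for (rep in 1:10) {
    d <- rand_residues(sample(1:40, 1), aa20)
    ref <- align_reference("sw", "MKVTW", d, 11, 1, b62)
    res <- align_striped("sw", db = d, gap_open = 11, gap_extend = 1,
      matrix = b62, profile = p, config = lane_config(16, 4))
    expect_equal(res$score, ref$score)
  }
})

test_that("profile construction rejects empty queries and mismatched use", {
  expect_error(build_profile("", toy), "empty query")
  p <- build_profile("ACGT", toy, "striped", lane_config(16, 4), cls = "nw")
  expect_error(
    align_scan("nw", db = "ACGT", matrix = toy, profile = p,
      config = lane_config(16, 4)),
    "layout 'striped'")
  expect_error(
    align_striped("nw", db = "ACGT", matrix = toy, profile = p,
      config = lane_config(16, 8)),
    "16-bit x 4 lanes")
})

test_that("every engine reproduces the reference exactly when unsaturated", {
  b62 <- builtin_matrix("BLOSUM62")
  set.seed(17)
  cases <- lapply(1:25, function(i) {
    list(q = rand_residues(sample(0:64, 1), aa20),
         d = rand_residues(sample(0:64, 1), aa20))
  })
  for (cls in c("nw", "sg", "sw")) {
    for (case in cases) {
      ref <- align_reference(cls, case$q, case$d, 11, 1, b62,
        want_stats = TRUE, want_table = TRUE, want_rowcol = TRUE)
      for (engine in c("striped", "scan", "diag")) {
        res <- engine_fn(engine)(cls, case$q, case$d, 11, 1, b62,
          config = lane_config(32, 8), want_stats = TRUE, want_table = TRUE,
          want_rowcol = TRUE)
        expect_false(res$saturated)
        expect_true(same_result(ref, res),
          info = sprintf("%s/%s m=%d n=%d", cls, engine,
            nchar(case$q), nchar(case$d)))
      }
    }
  }
})

test_that("results are invariant to lane count and width when representable", {
  b62 <- builtin_matrix("BLOSUM62")
  set.seed(19)
  q <- rand_residues(37, aa20)
  d <- rand_residues(53, aa20)
  for (cls in c("nw", "sg", "sw")) {
    ref <- align_reference(cls, q, d, 11, 1, b62, want_table = TRUE)
    for (engine in c("striped", "scan", "diag")) {
      for (w in c(16, 32)) {
        for (nl in c(2, 4, 8, 16)) {
          res <- engine_fn(engine)(cls, q, d, 11, 1, b62,
            config = lane_config(w, nl), want_table = TRUE)
          expect_false(res$saturated)
          expect_equal(res$score, ref$score,
            info = sprintf("%s %s w%d l%d", cls, engine, w, nl))
          expect_identical(res$table, ref$table)
        }
      }
    }
  }
})

test_that("8-bit local alignment saturates above the usable range and flags it", {
  long <- strrep("A", 300)
  for (engine in c("striped", "scan", "diag")) {
    res <- engine_fn(engine)("sw", long, long, 2, 1, toy5,
      config = lane_config(8, 16))
    expect_true(res$saturated, info = engine) # true score 1500 > 255
  }
  small <- strrep("A", 10)
  res <- align_striped("sw", small, small, 2, 1, toy5,
    config = lane_config(8, 16))
  expect_false(res$saturated) # 50 fits the biased 8-bit range
  expect_equal(res$score, 50)
})

test_that("empty database through a vector engine yields the reference edge case", {
  res <- align_striped("sw", "ACGT", "", 2, 1, toy, config = lane_config(16, 8))
  expect_equal(res$score, 0)
  expect_equal(res$run$corrective_passes, 0)
  expect_equal(res$run$columns, 0L)
})

test_that("saturation driver escalates widths until the exact score is representable", {
  long <- strrep("A", 300)
  res <- align_sat("sw", "striped", long, long, 2, 1, toy5)
  expect_equal(res$score, 1500)
  expect_false(res$saturated)
  expect_equal(attr(res, "widths_tried"), c(8L, 16L))
  small <- align_sat("sw", "striped", strrep("A", 10), strrep("A", 10), 2, 1,
    toy5)
  expect_equal(small$score, 50)
  expect_equal(attr(small, "widths_tried"), 8L)
  # global on long random pairs: 8-bit boundary is unrepresentable, so the
  # driver must escalate and still equal the reference
  b62 <- builtin_matrix("BLOSUM62")
  set.seed(29)
  for (engine in c("striped", "scan", "diag")) {
    q <- rand_residues(200, aa20)
    d <- rand_residues(200, aa20)
    ref <- align_reference("nw", q, d, 11, 1, b62)
    res <- align_sat("nw", engine, q, d, 11, 1, b62)
    expect_equal(res$score, ref$score, info = engine)
    expect_false(res$saturated)
    expect_lte(length(attr(res, "widths_tried")), 3L)
  }
})

test_that("whenever the flag is clear the score equals the reference (soundness)", {
  b62 <- builtin_matrix("BLOSUM62")
  set.seed(37)
  for (rep in 1:30) {
    q <- rand_residues(sample(1:120, 1), aa20)
    d <- rand_residues(sample(1:120, 1), aa20)
    cls <- sample(c("nw", "sg", "sw"), 1)
    engine <- sample(c("striped", "scan", "diag"), 1)
    res <- engine_fn(engine)(cls, q, d, 11, 1, b62, config = lane_config(8, 16))
    if (!res$saturated) {
      expect_equal(res$score, align_reference(cls, q, d, 11, 1, b62)$score,
        info = sprintf("%s %s rep %d", cls, engine, rep))
    }
  }
})

test_that("the scan engine sweeps every column exactly twice", {
  b62 <- builtin_matrix("BLOSUM62")
  set.seed(43)
  for (rep in 1:15) {
    q <- rand_residues(sample(1:80, 1), aa20)
    d <- rand_residues(sample(0:80, 1), aa20)
    cls <- sample(c("nw", "sg", "sw"), 1)
    res <- align_scan(cls, q, d, 11, 1, b62, config = lane_config(16, 8))
    expect_equal(res$run$sweeps, 2 * nchar(d),
      info = sprintf("rep %d n=%d", rep, nchar(d)))
  }
})

test_that("lazy-F corrective passes are bounded by the lane count per column", {
  b62 <- builtin_matrix("BLOSUM62")
  set.seed(47)
  for (rep in 1:15) {
    q <- rand_residues(sample(1:100, 1), aa20)
    d <- rand_residues(sample(1:100, 1), aa20)
    cls <- sample(c("nw", "sg", "sw"), 1)
    nl <- sample(c(4L, 8L, 16L), 1)
    res <- align_striped(cls, q, d, 11, 1, b62, config = lane_config(16, nl))
    expect_lte(res$run$corrective_passes, nl * nchar(d))
    expect_lte(res$run$max_corrective, nl)
  }
})

test_that("the origin shift does not increase corrective passes on average", {
  b62 <- builtin_matrix("BLOSUM62")
  set.seed(53)
  with_bias <- numeric(0)
  without_bias <- numeric(0)
  for (rep in 1:60) {
    q <- rand_residues(sample(1:60, 1), aa20)
    d <- rand_residues(sample(1:60, 1), aa20)
    rb <- align_striped("sw", q, d, 11, 1, b62, config = lane_config(8, 16),
      bias = TRUE)
    rn <- align_striped("sw", q, d, 11, 1, b62, config = lane_config(8, 16),
      bias = FALSE)
    with_bias <- c(with_bias, rb$run$corrective_passes)
    without_bias <- c(without_bias, rn$run$corrective_passes)
  }
  expect_lte(mean(with_bias), mean(without_bias))
})

test_that("a 1x1 problem is handled by the wavefront engine", {
  res <- align_diag("nw", "A", "A", 2, 1, toy, config = lane_config(16, 8),
    want_table = TRUE)
  ref <- align_reference("nw", "A", "A", 2, 1, toy, want_table = TRUE)
  expect_equal(res$score, ref$score)
  expect_identical(res$table, ref$table)
})
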