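#' Random sequence-pair corpus for cross-verification
#'
#' Residues are sampled uniformly over the matrix alphabet excluding the
#' `'*'` stop symbol; lengths are uniform over `length_range` (inclusive), so
#' empty and short sequences are covered. The global RNG state is left
#' untouched.
#'
#' @param n_pairs number of (query, database) pairs.
#' @param length_range integer bounds for sequence lengths.
#' @param matrix matrix supplying the alphabet.
#' @param seed RNG seed; identical seeds give identical corpora.
#' @return A tibble with columns `query` and `db`.
#' @export
random_corpus <- function(n_pairs = 200L, length_range = c(0L, 200L),
                          matrix = "BLOSUM62", seed = 42L) {
  matrix <- as_subst_matrix(matrix)
  alpha <- setdiff(matrix$alphabet, "*")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  rand_seq <- function() {
    len <- sample(seq.int(length_range[1L], length_range[2L]), 1L)
    if (len == 0L) "" else paste(sample(alpha, len, replace = TRUE),
      collapse = "")
  }
  tibble::tibble(
    query = vapply(seq_len(n_pairs), function(i) rand_seq(), character(1)),
    db = vapply(seq_len(n_pairs), function(i) rand_seq(), character(1))
  )
}

.default_runner <- function(engine, cls, query, db, gap_open, gap_extend,
                            matrix, config) {
  f <- switch(engine,
    striped = align_striped, scan = align_scan, diag = align_diag,
    stop(sprintf("unknown engine '%s'", engine), call. = FALSE))
  f(cls, query, db, gap_open, gap_extend, matrix, config = config,
    want_stats = TRUE, want_table = TRUE, want_rowcol = TRUE)
}

#' Cross-verify vector engines against the scalar reference
#'
#' Runs the exhaustive cross-product of corpus pairs, matrices, gap settings,
#' alignment classes, and vector configurations, comparing each vector result
#' against the scalar reference: score, end positions, statistics, and every
#' interior cell of the dynamic-programming table must match exactly. A
#' configuration that saturates at its tested width is automatically
#' escalated to the next width before comparison, so comparisons are always
#' made on representable results. Mismatches are report content, not errors.
#'
#' @param corpus a data frame with `query` and `db` columns (see
#'   [random_corpus()]).
#' @param matrices list of substitution matrices (objects or names).
#' @param gap_settings list of `c(open, extend)` pairs.
#' @param classes alignment classes to cover.
#' @param engines vector engines to cover.
#' @param widths element widths (bits) to cover.
#' @param lanes lane counts to cover.
#' @param runner the engine invocation hook; replaceable for fault-injection
#'   testing. Signature
#'   `runner(engine, cls, query, db, gap_open, gap_extend, matrix, config)`.
#' @return A `verification_report`: per-configuration outcomes with the first
#'   mismatching pair and cell, plus totals.
#' @examples
#' rep <- cross_verify(random_corpus(3, c(0, 30), seed = 7),
#'   gap_settings = list(c(11, 1)), widths = 16, lanes = 8)
#' rep$all_pass
#' @export
cross_verify <- function(corpus,
                         matrices = list(builtin_matrix("BLOSUM62")),
                         gap_settings = list(c(11, 1)),
                         classes = c("nw", "sg", "sw"),
                         engines = c("striped", "scan", "diag"),
                         widths = c(16, 32),
                         lanes = c(4, 8, 16),
                         runner = .default_runner) {
  stopifnot(nrow(corpus) > 0L)
  matrices <- lapply(matrices, as_subst_matrix)
  configs <- expand.grid(engine = engines, width = widths, lane = lanes,
    stringsAsFactors = FALSE)

  fails <- vector("list", nrow(configs))
  compared <- integer(nrow(configs))
  # the reference is computed once per (matrix, gaps, class, pair) and
  # compared against every lane configuration
  for (mi in seq_along(matrices)) {
    mat <- matrices[[mi]]
    for (gi in seq_along(gap_settings)) {
      go <- gap_settings[[gi]][1L]
      ge <- gap_settings[[gi]][2L]
      for (cls in classes) {
        for (p in seq_len(nrow(corpus))) {
          q <- corpus$query[p]
          d <- corpus$db[p]
          ref <- align_reference(cls, q, d, go, ge, mat,
            want_stats = TRUE, want_table = TRUE, want_rowcol = TRUE)
          for (ci in seq_len(nrow(configs))) {
            w <- configs$width[ci]
            nl <- configs$lane[ci]
            res <- runner(configs$engine[ci], cls, q, d, go, ge, mat,
              lane_config(w, nl))
            while (res$saturated && w < 64) {
              w <- w * 2L
              res <- runner(configs$engine[ci], cls, q, d, go, ge, mat,
                lane_config(w, nl))
            }
            compared[ci] <- compared[ci] + 1L
            mm <- .first_mismatch(ref, res)
            if (!is.null(mm) && is.null(fails[[ci]])) {
              fails[[ci]] <- c(list(pair = p, matrix = mat$name,
                gaps = sprintf("%d/%d", go, ge), class = cls), mm)
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, lapply(seq_len(nrow(configs)), function(ci) {
    fail <- fails[[ci]]
    tibble::tibble(
      engine = configs$engine[ci], width = configs$width[ci],
      lanes = configs$lane[ci],
      pass = is.null(fail), compared = compared[ci],
      first_mismatch = if (is.null(fail)) NA_character_ else {
        sprintf("pair %d, %s, gaps %s, class %s: %s", fail$pair, fail$matrix,
          fail$gaps, fail$class, fail$what)
      }
    )
  }))
  n_comparisons <- sum(compared)
  structure(
    list(
      configurations = out,
      configurations_tested = nrow(configs),
      n_comparisons = n_comparisons,
      n_pairs = nrow(corpus),
      all_pass = all(out$pass)
    ),
    class = "verification_report"
  )
}

# first differing component between a reference and an engine result;
# NULL if equal. Cell coordinates are 1-based (row = query, col = database).
.first_mismatch <- function(ref, res) {
  if (ref$score != res$score) {
    return(list(what = sprintf("score %s != %s", res$score, ref$score)))
  }
  if (ref$end_query != res$end_query || ref$end_ref != res$end_ref) {
    return(list(what = sprintf("ends (%d,%d) != (%d,%d)", res$end_query,
      res$end_ref, ref$end_query, ref$end_ref)))
  }
  if (!identical(ref$stats, res$stats)) {
    return(list(what = "stats differ"))
  }
  if (!identical(dim(ref$table), dim(res$table))) {
    return(list(what = "table dimensions differ"))
  }
  if (length(ref$table) && any(ref$table != res$table)) {
    idx <- which(ref$table != res$table, arr.ind = TRUE)[1L, ]
    return(list(what = sprintf("table cell (%d,%d): %d != %d", idx[1L],
      idx[2L], res$table[idx[1L], idx[2L]], ref$table[idx[1L], idx[2L]])))
  }
  if (!identical(ref$last_row, res$last_row) ||
      !identical(ref$last_col, res$last_col)) {
    return(list(what = "last row/column differ"))
  }
  NULL
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf(
    "<verification_report> %d configurations, %d comparisons over %d pairs: %s\n",
    x$configurations_tested, x$n_comparisons, x$n_pairs,
    if (x$all_pass) "ALL PASS" else "FAILURES"))
  bad <- x$configurations[!x$configurations$pass, , drop = FALSE]
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  FAIL %s w%d x%d: %s\n", bad$engine[i], bad$width[i],
        bad$lanes[i], bad$first_mismatch[i]))
    }
  }
  invisible(x)
}
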