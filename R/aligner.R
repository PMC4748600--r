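#' Batch pairwise alignment of FASTA/FASTQ files
#'
#' Mirrors a database-search aligner application: every query sequence is
#' aligned against every database sequence with the alignment routine named
#' by `fn` (see [parse_function_name()]). With a single input file
#' (`db_path = NULL`) the tool runs in self-comparison mode and aligns all
#' unordered distinct pairs of that file's sequences. An optional
#' suffix-array seed filter skips pairs that share no exact substring of at
#' least `seed_length` residues; skipped pairs are counted as filtered.
#'
#' One result row is produced per aligned pair: 1-based record indices,
#' sequence lengths, score, 0-based end positions, and (when the function
#' name requests stats) matches / similar / length. Output ordering is
#' deterministic — sorted by query index then database index — regardless of
#' `threads`. Throughput is reported in GCUPS (billion dynamic-programming
#' cell updates per second, a cell being one entry of the m-by-n table); the
#' timer spans alignment only, excluding sequence loading and index
#' construction.
#'
#' @param query_path FASTA or FASTQ file of query sequences.
#' @param db_path optional database file; omitted implies self-comparison.
#' @param fn alignment function name (the registry of
#'   [alignment_function_names()]).
#' @param threads worker processes for the alignment loop.
#' @param gap_open,gap_extend gap penalty magnitudes.
#' @param matrix substitution matrix: object, built-in name, or file path.
#' @param filter enable the exact-seed filter.
#' @param seed_length minimum shared seed length when the filter is enabled.
#' @param output optional path for the CSV results file.
#' @return An `aligner_run`: list with `results` (tibble), `report`
#'   (`aligner_report` with pair counts, cells, elapsed seconds, GCUPS), and
#'   `output`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "HEAGAWGHEE", ">b", "PAWHEAE", ">c", "AWGHE"), f)
#' run <- run_aligner(f, fn = "parasail_sw", gap_open = 10, gap_extend = 1)
#' run$results
#' @export
run_aligner <- function(query_path, db_path = NULL,
                        fn = "parasail_sw_striped_16", threads = 1L,
                        gap_open = 11, gap_extend = 1, matrix = "BLOSUM62",
                        filter = FALSE, seed_length = 7L, output = NULL) {
  # startup validation happens before any alignment work
  if (length(threads) != 1L || is.na(threads) || threads < 1L) {
    stop("threads must be a positive integer", call. = FALSE)
  }
  threads <- as.integer(threads)
  if (length(seed_length) != 1L || is.na(seed_length) || seed_length < 1L) {
    stop("seed_length must be a positive integer", call. = FALSE)
  }
  seed_length <- as.integer(seed_length)
  spec <- parse_function_name(fn)
  aligner <- resolve_function(spec)
  gp <- gap_penalties(gap_open, gap_extend)
  matrix <- as_subst_matrix(matrix)

  queries <- read_sequences(query_path)
  self_mode <- is.null(db_path)
  db <- if (self_mode) queries else read_sequences(db_path)

  enc_q <- lapply(seq_len(nrow(queries)),
    function(i) encode_sequence(queries$seq[i], matrix, queries$id[i]))
  enc_d <- if (self_mode) enc_q else {
    lapply(seq_len(nrow(db)),
      function(i) encode_sequence(db$seq[i], matrix, db$id[i]))
  }

  pairs <- if (self_mode) {
    if (nrow(queries) < 2L) {
      matrix(integer(0), ncol = 2L)
    } else {
      t(utils::combn(nrow(queries), 2L))
    }
  } else {
    as.matrix(expand.grid(qi = seq_len(nrow(queries)), di = seq_len(nrow(db))))
  }
  colnames(pairs) <- c("qi", "di")
  pairs <- pairs[order(pairs[, "qi"], pairs[, "di"]), , drop = FALSE]

  keep <- rep(TRUE, nrow(pairs))
  if (filter && nrow(pairs) > 0L) {
    idx_seqs <- if (self_mode) lapply(enc_q, `[[`, "residues") else {
      c(lapply(enc_q, `[[`, "residues"), lapply(enc_d, `[[`, "residues"))
    }
    sidx <- build_seed_index(lapply(idx_seqs, function(r) {
      structure(list(id = "s", residues = r, length = length(r)),
        class = "encoded_seq")
    }), matrix = matrix)
    off <- if (self_mode) 0L else length(enc_q)
    keep <- vapply(seq_len(nrow(pairs)), function(p) {
      longest_shared_seed(sidx, pairs[p, "qi"], off + pairs[p, "di"]) >=
        seed_length
    }, logical(1))
  }
  aligned_pairs <- pairs[keep, , drop = FALSE]

  # profile reuse: one striped/scan profile per distinct query
  profiles <- NULL
  if (spec$uses_profile && spec$engine %in% c("striped", "scan") &&
      !is.na(spec$width) && spec$width != "sat") {
    w <- as.integer(spec$width)
    cfg <- lane_config(w, max(1L, .backend_bits(spec$backend) %/% w))
    profiles <- vector("list", length(enc_q))
    for (qi in unique(aligned_pairs[, "qi"])) {
      if (enc_q[[qi]]$length > 0L) {
        profiles[[qi]] <- build_profile(enc_q[[qi]], matrix,
          layout = spec$engine, config = cfg, cls = spec$cls)
      }
    }
  }

  align_one <- function(p) {
    qi <- aligned_pairs[p, "qi"]
    di <- aligned_pairs[p, "di"]
    res <- aligner(enc_q[[qi]], enc_d[[di]], gp$open, gp$extend, matrix,
      profile = if (!is.null(profiles)) profiles[[qi]])
    row <- c(qi, di, enc_q[[qi]]$length, enc_d[[di]]$length, res$score,
      res$end_query, res$end_ref)
    if (spec$stats) {
      row <- c(row, res$stats$matches, res$stats$similar, res$stats$length)
    }
    row
  }

  t0 <- proc.time()[["elapsed"]]
  rows <- if (nrow(aligned_pairs) == 0L) {
    list()
  } else if (threads > 1L) {
    parallel::mclapply(seq_len(nrow(aligned_pairs)), align_one,
      mc.cores = threads)
  } else {
    lapply(seq_len(nrow(aligned_pairs)), align_one)
  }
  elapsed <- proc.time()[["elapsed"]] - t0

  cols <- c("query", "db", "query_length", "db_length", "score",
    "end_query", "end_ref")
  if (spec$stats) cols <- c(cols, "matches", "similar", "length")
  results <- if (length(rows) == 0L) {
    as_tibble(stats::setNames(
      as.data.frame(matrix(numeric(0), ncol = length(cols))), cols))
  } else {
    m <- do.call(rbind, rows)
    colnames(m) <- cols
    as_tibble(as.data.frame(m))
  }

  cells <- if (nrow(aligned_pairs) == 0L) 0 else {
    sum(as.numeric(results$query_length) * as.numeric(results$db_length))
  }
  report <- structure(
    list(
      pairs_total = nrow(pairs),
      pairs_aligned = nrow(aligned_pairs),
      pairs_filtered = nrow(pairs) - nrow(aligned_pairs),
      cells = cells,
      elapsed = elapsed,
      gcups = if (elapsed > 0) cells / elapsed / 1e9 else NA_real_,
      fn = canonical_function_name(spec),
      threads = threads
    ),
    class = "aligner_report"
  )

  if (!is.null(output)) {
    utils::write.csv(as.data.frame(results), output, row.names = FALSE,
      quote = FALSE)
  }
  structure(list(results = results, report = report, output = output),
    class = "aligner_run")
}

#' @export
print.aligner_report <- function(x, ...) {
  cat(sprintf("<aligner_report> %s, %d thread(s)\n", x$fn, x$threads))
  cat(sprintf("  pairs: %d total = %d aligned + %d filtered\n",
    x$pairs_total, x$pairs_aligned, x$pairs_filtered))
  cat(sprintf("  cells: %.0f, elapsed %.3f s, %s GCUPS\n",
    x$cells, x$elapsed,
    if (is.na(x$gcups)) "-" else sprintf("%.4f", x$gcups)))
  invisible(x)
}

#' @export
print.aligner_run <- function(x, ...) {
  print(x$report)
  cat(sprintf("  %d result rows%s\n", nrow(x$results),
    if (is.null(x$output)) "" else paste0(" -> ", x$output)))
  invisible(x)
}
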