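#' Emulated SIMD lane configuration
#'
#' An alignment engine operates on an emulated vector register split into
#' `lanes` integer elements of `width` bits each; e.g. 16 lanes of 8 bits
#' emulate a 128-bit register. All lane arithmetic saturates at the signed
#' extremes of the element width (or at `[0, 2^width - 1]` in the
#' origin-shifted local 8-bit mode).
#'
#' @param width element width in bits: 8, 16, 32, or 64.
#' @param lanes positive lane count; independent of host hardware.
#' @return A `lane_config` with `element_bits`, `lanes`, `min_value`,
#'   `max_value`.
#' @examples
#' lane_config(8, 16) # a 128-bit register of 8-bit elements
#' @export
lane_config <- function(width = 16, lanes = 8) {
  if (!width %in% c(8, 16, 32, 64)) {
    stop("element width must be one of 8, 16, 32, 64", call. = FALSE)
  }
  if (length(lanes) != 1L || is.na(lanes) || lanes < 1 || lanes != round(lanes)) {
    stop("lane count must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      element_bits = as.integer(width),
      lanes = as.integer(lanes),
      min_value = -(2^(width - 1)),
      max_value = 2^(width - 1) - 1
    ),
    class = "lane_config"
  )
}

#' @export
print.lane_config <- function(x, ...) {
  cat(sprintf("<lane_config> %d lanes x %d bits (%d-bit register)\n",
    x$lanes, x$element_bits, x$lanes * x$element_bits))
  invisible(x)
}

.cls_code <- function(cls) {
  cls <- match.arg(cls, c("nw", "sg", "sw"))
  c(nw = 0L, sg = 1L, sw = 2L)[[cls]]
}

.use_bias <- function(cls, width, bias) {
  isTRUE(bias) && cls == "sw" && width == 8L
}

#' Precompute a striped or scan query profile
#'
#' The profile arranges the query's substitution scores per alphabet symbol so
#' that lane `l` of segment word `k` holds query position `k + l*t`,
#' `t = ceiling(m / lanes)`. Padding slots beyond the query length hold the
#' domain floor so a padded lane can never win a maximum. The profile is
#' reusable across database sequences aligned with the same matrix, penalties,
#' and width. In local 8-bit mode the profile records the origin shift (bias),
#' under which the signed floor plus one is treated as zero.
#'
#' @param query residue text or an [encode_sequence()] result; must be
#'   nonempty.
#' @param matrix a [subst_matrix()], built-in name, or matrix file path.
#' @param layout `"striped"` or `"scan"` (the scan engine consumes the same
#'   striped arrangement; the tag records the intended engine and is validated
#'   at use time).
#' @param config a [lane_config()].
#' @param cls alignment class the profile is intended for: `"nw"`, `"sg"`, or
#'   `"sw"`.
#' @param bias logical; apply the origin shift in local 8-bit mode.
#' @return A `query_profile`.
#' @export
build_profile <- function(query, matrix, layout = c("striped", "scan"),
                          config = lane_config(), cls = c("sw", "nw", "sg"),
                          bias = TRUE) {
  layout <- match.arg(layout)
  cls <- match.arg(cls)
  matrix <- as_subst_matrix(matrix)
  query <- as_encoded(query, matrix, id = "query")
  if (query$length == 0L) {
    stop("cannot build a query profile for an empty query", call. = FALSE)
  }
  width <- config$element_bits
  biased <- .use_bias(cls, width, bias)
  data <- cpp_build_profile(query$residues, matrix$scores, config$lanes,
    width, biased)
  structure(
    list(
      query = query,
      matrix = matrix,
      layout = layout,
      width = width,
      lanes = config$lanes,
      cls = cls,
      bias = if (biased) as.integer(-(2^(width - 1)) + 1) else 0L,
      segment_length = as.integer(ceiling(query$length / config$lanes)),
      data = data
    ),
    class = "query_profile"
  )
}

#' @export
print.query_profile <- function(x, ...) {
  cat(sprintf(
    "<query_profile> %s: %d residues, %s layout, %d-bit x %d lanes (t = %d), bias %d\n",
    x$query$id, x$query$length, x$layout, x$width, x$lanes,
    x$segment_length, x$bias))
  invisible(x)
}

#' Decode one position of a query profile
#'
#' Inverse of the striped mapping: returns the substitution score the profile
#' stores for `symbol` against query position `pos` (1-based).
#'
#' @param profile a [build_profile()] result.
#' @param symbol residue symbol.
#' @param pos 1-based query position.
#' @return The stored integer score.
#' @export
profile_score <- function(profile, symbol, pos) {
  stopifnot(inherits(profile, "query_profile"))
  p <- pos - 1L
  t <- profile$segment_length
  k <- p %% t
  l <- p %/% t
  ci <- match(toupper(symbol), profile$matrix$alphabet)
  if (is.na(ci)) stop("symbol not in profile alphabet", call. = FALSE)
  as.integer(profile$data[ci, k * profile$lanes + l + 1L])
}

.make_result <- function(raw, cls, want_stats, want_table, want_rowcol,
                         engine, width = NA_integer_, lanes = NA_integer_,
                         bias = FALSE) {
  res <- list(
    score = raw$score,
    end_query = raw$end_query,
    end_ref = raw$end_ref,
    class_tag = cls,
    saturated = raw$saturated,
    stats = if (want_stats) {
      list(matches = raw$matches, similar = raw$similar, length = raw$length)
    },
    table = if (want_table) raw$table,
    last_row = if (want_rowcol) raw$last_row,
    last_col = if (want_rowcol) raw$last_col,
    run = list(
      engine = engine,
      corrective_passes = raw$corrective_passes,
      max_corrective = raw$max_corrective,
      sweeps = raw$sweeps,
      columns = raw$columns,
      width = width,
      lanes = lanes,
      bias = bias
    )
  )
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> %s score %s, end (%d, %d)%s [%s engine]\n",
    toupper(x$class_tag), format(x$score), x$end_query, x$end_ref,
    if (isTRUE(x$saturated)) " [SATURATED]" else "", x$run$engine))
  if (!is.null(x$stats)) {
    cat(sprintf("  stats: %d matches, %d similar, length %d\n",
      x$stats$matches, x$stats$similar, x$stats$length))
  }
  invisible(x)
}

.align_common <- function(engine, cls, query, db, gap_open, gap_extend, matrix,
                          width, lanes, bias, want_stats, want_table,
                          want_rowcol) {
  gp <- gap_penalties(gap_open, gap_extend)
  matrix <- as_subst_matrix(matrix)
  query <- as_encoded(query, matrix, id = "query")
  db <- as_encoded(db, matrix, id = "db")
  biased <- .use_bias(cls, width, bias)
  raw <- cpp_align(engine, .cls_code(cls), query$residues, db$residues,
    matrix$scores, gp$open, gp$extend, as.integer(width), as.integer(lanes),
    biased, want_stats, want_table, want_rowcol)
  .make_result(raw, match.arg(cls, c("nw", "sg", "sw")), want_stats,
    want_table, want_rowcol, engine, as.integer(width), as.integer(lanes),
    biased)
}

#' Align two sequences
#'
#' `align_reference()` is the scalar dynamic-programming oracle for all three
#' alignment classes; every vector engine is verified against it cell by cell.
#' `align_striped()`, `align_scan()`, and `align_diag()` run the lane-parallel
#' engines in a fixed-width saturating integer domain and return results
#' identical to the reference whenever no saturation occurs; otherwise the
#' `saturated` flag is set. `align_sat()` is the width-escalation driver: it
#' runs at 8 bits and retries at 16 and then 32 bits while the result is
#' saturated.
#'
#' Classes: `"nw"` global alignment (score at the final cell; the boundary
#' follows the gap function), `"sg"` semi-global (end gaps in either sequence
#' are free; score is the maximum over the last row and column), `"sw"` local
#' (scores clamped at zero; maximum over all cells). End positions are 0-based
#' inclusive residue indices of the optimal cell under the tie-break rule:
#' smallest `end_ref`, then smallest `end_query`. Requested tables and
#' row/column vectors cover interior cells only.
#'
#' @param cls `"nw"`, `"sg"`, or `"sw"`.
#' @param query,db residue text or [encode_sequence()] results.
#' @param gap_open,gap_extend nonnegative gap penalty magnitudes; a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param matrix a [subst_matrix()], built-in name, or matrix file path.
#' @param want_stats,want_table,want_rowcol which result variants to populate.
#' @return An `alignment_result`: `score`, `end_query`, `end_ref`,
#'   `saturated`, optional `stats` (matches / similar / length), `table`,
#'   `last_row` / `last_col`, and a `run` record (engine, corrective lazy-F
#'   passes, column sweeps, lane geometry).
#' @examples
#' align_reference("sw", "HEAGAWGHEE", "PAWHEAE", 10, 1, "BLOSUM62")$score
#' @export
align_reference <- function(cls, query, db, gap_open = 11, gap_extend = 1,
                            matrix = "BLOSUM62", want_stats = FALSE,
                            want_table = FALSE, want_rowcol = FALSE) {
  .align_common("reference", cls, query, db, gap_open, gap_extend, matrix,
    64L, 1L, FALSE, want_stats, want_table, want_rowcol)
}

#' @rdname align_reference
#' @param profile an optional [build_profile()] result; when given, its query,
#'   matrix, and width are used and must agree with `config`.
#' @param config a [lane_config()].
#' @param bias logical; apply the origin shift in local 8-bit mode (the
#'   default). Disabling it is a diagnostic that runs the signed-domain
#'   computation for comparison of corrective-pass counts.
#' @export
align_striped <- function(cls, query = NULL, db, gap_open = 11, gap_extend = 1,
                          matrix = "BLOSUM62", profile = NULL,
                          config = lane_config(), bias = TRUE,
                          want_stats = FALSE, want_table = FALSE,
                          want_rowcol = FALSE) {
  .align_vector("striped", cls, query, db, gap_open, gap_extend, matrix,
    profile, config, bias, want_stats, want_table, want_rowcol)
}

#' @rdname align_reference
#' @export
align_scan <- function(cls, query = NULL, db, gap_open = 11, gap_extend = 1,
                       matrix = "BLOSUM62", profile = NULL,
                       config = lane_config(), bias = TRUE,
                       want_stats = FALSE, want_table = FALSE,
                       want_rowcol = FALSE) {
  .align_vector("scan", cls, query, db, gap_open, gap_extend, matrix,
    profile, config, bias, want_stats, want_table, want_rowcol)
}

#' @rdname align_reference
#' @export
align_diag <- function(cls, query, db, gap_open = 11, gap_extend = 1,
                       matrix = "BLOSUM62", config = lane_config(),
                       bias = TRUE, want_stats = FALSE, want_table = FALSE,
                       want_rowcol = FALSE) {
  .align_vector("diag", cls, query, db, gap_open, gap_extend, matrix,
    NULL, config, bias, want_stats, want_table, want_rowcol)
}

.align_vector <- function(engine, cls, query, db, gap_open, gap_extend,
                          matrix, profile, config, bias, want_stats,
                          want_table, want_rowcol) {
  cls <- match.arg(cls, c("nw", "sg", "sw"))
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "query_profile"))
    expected <- if (engine == "scan") "scan" else "striped"
    if (profile$layout != expected) {
      stop(sprintf("profile layout '%s' cannot drive the %s engine",
        profile$layout, engine), call. = FALSE)
    }
    if (profile$width != config$element_bits || profile$lanes != config$lanes) {
      stop(sprintf(
        "profile built for %d-bit x %d lanes but config requests %d-bit x %d lanes",
        profile$width, profile$lanes, config$element_bits, config$lanes),
        call. = FALSE)
    }
    query <- profile$query
    matrix <- profile$matrix
    bias <- profile$bias != 0L
  }
  if (is.null(query)) {
    stop("either 'query' or 'profile' must be supplied", call. = FALSE)
  }
  .align_common(engine, cls, query, db, gap_open, gap_extend, matrix,
    config$element_bits, config$lanes, bias, want_stats, want_table,
    want_rowcol)
}

#' @rdname align_reference
#' @param engine which vector engine the saturation driver should use.
#' @param register_bits emulated register width in bits; the lane count at
#'   each attempted element width is `register_bits / width`.
#' @export
align_sat <- function(cls, engine = c("striped", "scan", "diag"), query, db,
                      gap_open = 11, gap_extend = 1, matrix = "BLOSUM62",
                      register_bits = 256, bias = TRUE, want_stats = FALSE,
                      want_table = FALSE, want_rowcol = FALSE) {
  engine <- match.arg(engine)
  widths <- c(8L, 16L, 32L)
  res <- NULL
  for (w in widths) {
    cfg <- lane_config(w, max(1L, register_bits %/% w))
    res <- .align_vector(engine, cls, query, db, gap_open, gap_extend, matrix,
      NULL, cfg, bias, want_stats, want_table, want_rowcol)
    attr(res, "widths_tried") <- widths[seq_len(match(w, widths))]
    if (!res$saturated) return(res)
  }
  res
}
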