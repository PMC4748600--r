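#' Alignment function names and dispatch
#'
#' Alignment routines are addressed by Parasail-style function names built
#' from underscore-separated components, in this fixed order:
#'
#' `parasail_(nw|sg|sw)[_stats][_(table|rowcol)][_(striped|scan|diag)][_profile][_(sse2_128|sse41_128|avx2_256|knc_512)]_(8|16|32|64|sat)`
#'
#' The prefix and the class are required. `stats` requests alignment
#' statistics; `table` or `rowcol` request the full dynamic-programming table
#' or its last row and column. A vector engine component selects striped,
#' prefix-scan, or anti-diagonal lane-parallel evaluation; without one the
#' scalar reference implementation is used and no further components are
#' allowed. `profile` (striped and scan only) marks the query-profile-reusing
#' entry point. The instruction-set component is honoured as a lane-geometry
#' preset (register bits / element bits lanes); when omitted the backend is
#' `auto`, which binds the widest emulated register (256 bits). The trailing
#' integer width is required for vector engines; `sat` selects the
#' width-escalation driver (8-bit first, retrying at 16 and then 32 bits on
#' overflow).
#'
#' @param name a function name, e.g. `"parasail_sw_striped_profile_sse41_128_16"`.
#' @return `parse_function_name()`: a `function_spec` with fields `cls`,
#'   `stats`, `variant`, `engine`, `uses_profile`, `backend`, `width`.
#' @examples
#' parse_function_name("parasail_sw")
#' parse_function_name("parasail_sg_stats_scan_avx2_256_sat")
#' @export
parse_function_name <- function(name) {
  name <- as.character(name)[1L]
  toks <- strsplit(name, "_", fixed = TRUE)[[1L]]
  bad <- function(tok, why) {
    stop(sprintf("invalid function name '%s': %s at component '%s'",
      name, why, tok), call. = FALSE)
  }
  if (length(toks) < 2L || toks[1L] != "parasail") {
    stop(sprintf("invalid function name '%s': missing 'parasail' prefix", name),
      call. = FALSE)
  }
  i <- 2L
  nxt <- function() if (i <= length(toks)) toks[i] else NA_character_
  if (!nxt() %in% c("nw", "sg", "sw")) {
    bad(ifelse(is.na(nxt()), "<end>", nxt()), "expected alignment class nw/sg/sw")
  }
  cls <- nxt(); i <- i + 1L
  stats <- FALSE
  if (identical(nxt(), "stats")) { stats <- TRUE; i <- i + 1L }
  variant <- "none"
  if (nxt() %in% c("table", "rowcol")) { variant <- nxt(); i <- i + 1L }
  engine <- "reference"
  if (nxt() %in% c("striped", "scan", "diag")) { engine <- nxt(); i <- i + 1L }
  uses_profile <- FALSE
  if (identical(nxt(), "profile")) {
    if (!engine %in% c("striped", "scan")) {
      bad("profile", "profile applies only to the striped and scan engines")
    }
    uses_profile <- TRUE; i <- i + 1L
  }
  backend <- "auto"
  isa <- c(sse2 = 128L, sse41 = 128L, avx2 = 256L, knc = 512L)
  if (nxt() %in% names(isa)) {
    if (engine == "reference") bad(nxt(), "instruction set requires a vector engine")
    tag <- nxt(); i <- i + 1L
    bits <- isa[[tag]]
    if (!identical(nxt(), as.character(bits))) {
      bad(ifelse(is.na(nxt()), "<end>", nxt()),
        sprintf("instruction set '%s' must be followed by '%d'", tag, bits))
    }
    backend <- paste0(tag, "_", bits); i <- i + 1L
  }
  width <- NA_character_
  if (engine != "reference") {
    if (!nxt() %in% c("8", "16", "32", "64", "sat")) {
      bad(ifelse(is.na(nxt()), "<end>", nxt()),
        "vector engines require a trailing width (8/16/32/64/sat)")
    }
    width <- nxt(); i <- i + 1L
  }
  if (i <= length(toks)) {
    bad(toks[i], "unexpected trailing component")
  }
  structure(
    list(cls = cls, stats = stats, variant = variant, engine = engine,
      uses_profile = uses_profile,
      backend = if (engine == "reference") NA_character_ else backend,
      width = width),
    class = "function_spec"
  )
}

#' @rdname parse_function_name
#' @param spec a `function_spec`.
#' @return `canonical_function_name()`: the canonical name string; parsing it
#'   back yields an identical spec.
#' @export
canonical_function_name <- function(spec) {
  stopifnot(inherits(spec, "function_spec"))
  parts <- c("parasail", spec$cls)
  if (spec$stats) parts <- c(parts, "stats")
  if (spec$variant != "none") parts <- c(parts, spec$variant)
  if (spec$engine != "reference") {
    parts <- c(parts, spec$engine)
    if (spec$uses_profile) parts <- c(parts, "profile")
    if (!is.na(spec$backend) && spec$backend != "auto") parts <- c(parts, spec$backend)
    parts <- c(parts, spec$width)
  }
  paste(parts, collapse = "_")
}

#' @export
print.function_spec <- function(x, ...) {
  cat(sprintf("<function_spec> %s\n", canonical_function_name(x)))
  cat(sprintf("  class %s, engine %s, stats %s, variant %s, backend %s, width %s\n",
    x$cls, x$engine, x$stats, x$variant,
    ifelse(is.na(x$backend), "-", x$backend),
    ifelse(is.na(x$width), "-", x$width)))
  invisible(x)
}

.backend_bits <- function(backend) {
  if (is.na(backend) || backend == "auto") return(256L)
  as.integer(sub("^.*_", "", backend))
}

#' Resolve a function name or spec to an executable alignment operation
#'
#' Backend tags are honoured as lane-geometry presets: the lane count is
#' register bits divided by element bits (e.g. `sse41_128` at width 8 gives
#' 16 lanes). `auto` binds the widest emulated register, 256 bits. Width
#' `sat` binds the saturation-escalation driver.
#'
#' @param x a function name string or a `function_spec`.
#' @return A function `f(query, db, gap_open, gap_extend, matrix,
#'   profile = NULL)` returning an `alignment_result`, with the `function_spec`
#'   attached as attribute `"spec"`.
#' @examples
#' f <- resolve_function("parasail_nw_scan_avx2_256_16")
#' f("ACGT", "ACGT", 2, 1, builtin_matrix("BLOSUM62"))$score
#' @export
resolve_function <- function(x) {
  spec <- if (inherits(x, "function_spec")) x else parse_function_name(x)
  want_stats <- spec$stats
  want_table <- spec$variant == "table"
  want_rowcol <- spec$variant == "rowcol"
  cls <- spec$cls
  engine <- spec$engine
  bits <- .backend_bits(spec$backend)
  fn <- if (engine == "reference") {
    function(query, db, gap_open = 11, gap_extend = 1, matrix = "BLOSUM62",
             profile = NULL) {
      align_reference(cls, query, db, gap_open, gap_extend, matrix,
        want_stats = want_stats, want_table = want_table,
        want_rowcol = want_rowcol)
    }
  } else if (spec$width == "sat") {
    function(query, db, gap_open = 11, gap_extend = 1, matrix = "BLOSUM62",
             profile = NULL) {
      align_sat(cls, engine, query, db, gap_open, gap_extend, matrix,
        register_bits = bits, want_stats = want_stats,
        want_table = want_table, want_rowcol = want_rowcol)
    }
  } else {
    w <- as.integer(spec$width)
    cfg <- lane_config(w, max(1L, bits %/% w))
    switch(engine,
      striped = function(query, db, gap_open = 11, gap_extend = 1,
                         matrix = "BLOSUM62", profile = NULL) {
        align_striped(cls, query, db, gap_open, gap_extend, matrix,
          profile = profile, config = cfg, want_stats = want_stats,
          want_table = want_table, want_rowcol = want_rowcol)
      },
      scan = function(query, db, gap_open = 11, gap_extend = 1,
                      matrix = "BLOSUM62", profile = NULL) {
        align_scan(cls, query, db, gap_open, gap_extend, matrix,
          profile = profile, config = cfg, want_stats = want_stats,
          want_table = want_table, want_rowcol = want_rowcol)
      },
      diag = function(query, db, gap_open = 11, gap_extend = 1,
                      matrix = "BLOSUM62", profile = NULL) {
        align_diag(cls, query, db, gap_open, gap_extend, matrix,
          config = cfg, want_stats = want_stats, want_table = want_table,
          want_rowcol = want_rowcol)
      },
      stop(sprintf("engine '%s' is not implemented", engine), call. = FALSE)
    )
  }
  attr(fn, "spec") <- spec
  fn
}

#' Enumerate every valid alignment function name
#'
#' The full registry of canonical names accepted by [resolve_function()] and
#' by the batch aligner's `-a` argument.
#'
#' @return A character vector of names.
#' @export
alignment_function_names <- function() {
  out <- character(0)
  backends <- c("auto", "sse2_128", "sse41_128", "avx2_256", "knc_512")
  widths <- c("8", "16", "32", "64", "sat")
  for (cls in c("nw", "sg", "sw"))
    for (st in c(FALSE, TRUE))
      for (var in c("none", "table", "rowcol")) {
        out <- c(out, canonical_function_name(structure(
          list(cls = cls, stats = st, variant = var, engine = "reference",
            uses_profile = FALSE, backend = NA_character_,
            width = NA_character_), class = "function_spec")))
        for (eng in c("striped", "scan", "diag"))
          for (prof in if (eng == "diag") FALSE else c(FALSE, TRUE))
            for (be in backends)
              for (w in widths) {
                out <- c(out, canonical_function_name(structure(
                  list(cls = cls, stats = st, variant = var, engine = eng,
                    uses_profile = prof, backend = be, width = w),
                  class = "function_spec")))
              }
      }
  unique(out)
}
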