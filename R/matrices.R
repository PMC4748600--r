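#' Substitution matrices, gap penalties, and sequence encoding
#'
#' A `subst_matrix` holds an ordered residue alphabet (uppercase letters plus
#' an optional `'*'` stop symbol) and a square integer score table indexed by
#' residue pair. The eight classic protein matrices (BLOSUM45/50/62/80/90,
#' PAM30/70/250, as distributed by NCBI) ship with the package; arbitrary
#' matrices can be read from NCBI flat-format text files. Built-in matrices
#' are symmetric; parsed matrices need not be, and any asymmetry is preserved.
#'
#' @param alphabet character vector of single residue symbols, in order.
#' @param scores integer matrix, `length(alphabet)` on each side;
#'   `scores[i, j]` is the score for substituting symbol `i` with symbol `j`.
#' @param name matrix name used in printing and profiles.
#' @return An object of class `subst_matrix` with fields `name`, `alphabet`,
#'   `scores`, and cached `min_score` / `max_score`.
#' @examples
#' m <- subst_matrix(c("A", "C"), matrix(c(2L, -1L, -1L, 2L), 2), "toy")
#' m$max_score
#' @export
subst_matrix <- function(alphabet, scores, name = "custom") {
  alphabet <- as.character(alphabet)
  if (length(alphabet) < 1L) {
    stop("alphabet must contain at least one symbol", call. = FALSE)
  }
  if (any(nchar(alphabet) != 1L)) {
    stop("alphabet symbols must be single characters", call. = FALSE)
  }
  if (anyDuplicated(alphabet)) {
    stop("alphabet symbols must be unique", call. = FALSE)
  }
  scores <- as.matrix(scores)
  if (nrow(scores) != length(alphabet) || ncol(scores) != length(alphabet)) {
    stop("scores must be a square matrix with side length |alphabet|",
      call. = FALSE)
  }
  if (any(is.na(scores)) || any(scores != round(scores))) {
    stop("scores must be integers with no missing values", call. = FALSE)
  }
  storage.mode(scores) <- "integer"
  dimnames(scores) <- list(alphabet, alphabet)
  structure(
    list(
      name = as.character(name)[1L],
      alphabet = alphabet,
      scores = scores,
      min_score = min(scores),
      max_score = max(scores)
    ),
    class = "subst_matrix"
  )
}

#' @export
print.subst_matrix <- function(x, ...) {
  cat(sprintf(
    "<subst_matrix> %s: %d symbols (%s), scores in [%d, %d]\n",
    x$name, length(x$alphabet), paste(x$alphabet, collapse = ""),
    x$min_score, x$max_score
  ))
  invisible(x)
}

#' Parse a substitution matrix in NCBI flat-text format
#'
#' The format is the one used by the matrices on the NCBI FTP site: any number
#' of `#` comment lines, one header row listing the residue symbols, then one
#' row per residue consisting of the leading symbol followed by one integer
#' per alphabet column. Row symbols must match the header order.
#'
#' @param text character scalar (entire file content) or character vector of
#'   lines.
#' @param name name recorded in the returned matrix.
#' @return A [subst_matrix()].
#' @examples
#' parse_matrix("#toy\n A C\nA 2 -1\nC -1 2")
#' @export
parse_matrix <- function(text, name = "parsed") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  keep <- !grepl("^\\s*#", lines) & !grepl("^\\s*$", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L) {
    stop("matrix parse error: empty input (no header line found)", call. = FALSE)
  }
  header <- strsplit(trimws(body[1L]), "\\s+")[[1L]]
  if (any(nchar(header) != 1L)) {
    stop(sprintf("matrix parse error at line %d: header symbols must be single characters",
      lineno[1L]), call. = FALSE)
  }
  k <- length(header)
  rows <- body[-1L]
  if (length(rows) != k) {
    stop(sprintf(
      "matrix parse error: header lists %d symbols but %d score rows follow",
      k, length(rows)), call. = FALSE)
  }
  scores <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    toks <- strsplit(trimws(rows[i]), "\\s+")[[1L]]
    ln <- lineno[i + 1L]
    if (toks[1L] != header[i]) {
      stop(sprintf(
        "matrix parse error at line %d: row symbol '%s' does not match header symbol '%s'",
        ln, toks[1L], header[i]), call. = FALSE)
    }
    if (length(toks) != k + 1L) {
      stop(sprintf(
        "matrix parse error at line %d: expected %d scores, found %d",
        ln, k, length(toks) - 1L), call. = FALSE)
    }
    vals <- suppressWarnings(as.integer(toks[-1L]))
    if (any(is.na(vals)) ||
        any(suppressWarnings(as.numeric(toks[-1L])) != vals)) {
      stop(sprintf("matrix parse error at line %d: non-integer score cell", ln),
        call. = FALSE)
    }
    scores[i, ] <- vals
  }
  subst_matrix(header, scores, name = name)
}

#' Read a substitution matrix file
#'
#' @param path path to an NCBI flat-format matrix file.
#' @param name matrix name; defaults to the file base name without extension.
#' @return A [subst_matrix()].
#' @export
read_matrix <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("matrix file not found: %s", path), call. = FALSE)
  }
  if (is.null(name)) {
    name <- sub("\\.[^.]*$", "", basename(path))
  }
  parse_matrix(readLines(path, warn = FALSE), name = name)
}

#' Serialize a substitution matrix to NCBI flat-text format
#'
#' `format_matrix()` returns the text; `write_matrix()` writes it to a file.
#' The output re-parses to an identical matrix.
#'
#' @param matrix a [subst_matrix()].
#' @return `format_matrix()`: a character scalar. `write_matrix()`: the path,
#'   invisibly.
#' @export
format_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "subst_matrix"))
  wid <- max(nchar(as.character(matrix$scores)))
  fmt <- sprintf("%%%ds", wid)
  header <- paste0(" ", paste(sprintf(fmt, matrix$alphabet), collapse = " "))
  rows <- vapply(seq_along(matrix$alphabet), function(i) {
    paste0(matrix$alphabet[i], " ",
      paste(sprintf(fmt, matrix$scores[i, ]), collapse = " "))
  }, character(1))
  paste0(paste(c(paste0("# ", matrix$name), header, rows), collapse = "\n"), "\n")
}

#' @rdname format_matrix
#' @param path output file path.
#' @export
write_matrix <- function(matrix, path) {
  writeLines(sub("\n$", "", format_matrix(matrix)), path)
  invisible(path)
}

.builtin_names <- c(
  "BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM90",
  "PAM30", "PAM70", "PAM250"
)

.builtin_cache <- new.env(parent = emptyenv())

#' Built-in substitution matrices
#'
#' The BLOSUM45, BLOSUM50, BLOSUM62, BLOSUM80, BLOSUM90, PAM30, PAM70, and
#' PAM250 matrices in their standard NCBI form (24-symbol alphabet including
#' the B/Z ambiguity codes, X, and the `'*'` stop symbol). Lookup is
#' case-insensitive.
#'
#' @param name one of the eight names, in any case.
#' @return A [subst_matrix()].
#' @examples
#' builtin_matrix("blosum62")
#' @export
builtin_matrix <- function(name) {
  canon <- toupper(as.character(name)[1L])
  if (!canon %in% .builtin_names) {
    stop(sprintf(
      "unknown built-in matrix '%s'; valid names: %s",
      name, paste(.builtin_names, collapse = ", ")), call. = FALSE)
  }
  if (is.null(.builtin_cache[[canon]])) {
    path <- system.file("extdata", "matrices", paste0(canon, ".txt"),
      package = "lanealign", mustWork = TRUE)
    .builtin_cache[[canon]] <- read_matrix(path, name = canon)
  }
  .builtin_cache[[canon]]
}

#' @rdname builtin_matrix
#' @export
builtin_matrix_names <- function() .builtin_names

#' Resolve a matrix argument
#'
#' Accepts a `subst_matrix`, a built-in name, or a file path.
#' @noRd
as_subst_matrix <- function(matrix) {
  if (inherits(matrix, "subst_matrix")) return(matrix)
  if (is.character(matrix) && length(matrix) == 1L) {
    if (toupper(matrix) %in% .builtin_names) return(builtin_matrix(matrix))
    if (file.exists(matrix)) return(read_matrix(matrix))
    stop(sprintf(
      "'%s' is neither a built-in matrix name nor an existing file", matrix),
      call. = FALSE)
  }
  stop("matrix must be a subst_matrix, a built-in name, or a file path",
    call. = FALSE)
}

#' Affine gap penalties
#'
#' Penalties are stored as nonnegative magnitudes and subtracted during the
#' dynamic programming: a gap of length L costs `open + L * extend`, so a
#' length-1 gap costs `open + extend`. Under this convention the BLAST default
#' of open 11, extend 1 charges 12 for a single-residue gap.
#'
#' @param open nonnegative integer gap-open magnitude.
#' @param extend nonnegative integer gap-extension magnitude.
#' @return A list with class `gap_penalties`.
#' @export
gap_penalties <- function(open, extend) {
  if (length(open) != 1L || length(extend) != 1L ||
      is.na(open) || is.na(extend) || open < 0 || extend < 0 ||
      open != round(open) || extend != round(extend)) {
    stop("gap penalties must be single nonnegative integers", call. = FALSE)
  }
  structure(list(open = as.integer(open), extend = as.integer(extend)),
    class = "gap_penalties")
}

#' Encode a raw residue string against a matrix alphabet
#'
#' Residues are uppercased and mapped to 0-based alphabet indices. Symbols
#' absent from the alphabet fall back to the `'X'` (any) row when the alphabet
#' has one; otherwise encoding fails, reporting the position and symbol.
#'
#' @param raw residue text (one string).
#' @param matrix a [subst_matrix()], built-in name, or matrix file path.
#' @param id sequence identifier.
#' @return An `encoded_seq`: list with `id`, `residues` (0-based integer
#'   indices), and `length`.
#' @examples
#' toy <- parse_matrix("#t\n A C\nA 2 -1\nC -1 2")
#' encode_sequence("AC", toy)$residues
#' @export
encode_sequence <- function(raw, matrix, id = "seq") {
  matrix <- as_subst_matrix(matrix)
  raw <- toupper(as.character(raw)[1L])
  if (is.na(raw)) raw <- ""
  chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
  idx <- match(chars, matrix$alphabet)
  if (anyNA(idx)) {
    xi <- match("X", matrix$alphabet)
    if (is.na(xi)) {
      bad <- which(is.na(idx))[1L]
      stop(sprintf(
        "cannot encode symbol '%s' at position %d: not in alphabet and no 'X' fallback",
        chars[bad], bad), call. = FALSE)
    }
    idx[is.na(idx)] <- xi
  }
  structure(
    list(id = as.character(id)[1L], residues = as.integer(idx - 1L),
      length = length(chars)),
    class = "encoded_seq"
  )
}

#' @rdname encode_sequence
#' @param seq an `encoded_seq`.
#' @return `decode_sequence()`: the residue text implied by the indices.
#' @export
decode_sequence <- function(seq, matrix) {
  matrix <- as_subst_matrix(matrix)
  stopifnot(inherits(seq, "encoded_seq"))
  paste(matrix$alphabet[seq$residues + 1L], collapse = "")
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat(sprintf("<encoded_seq> %s: %d residues\n", x$id, x$length))
  invisible(x)
}

#' Coerce query/database arguments for the aligners
#' @noRd
as_encoded <- function(x, matrix, id = "seq") {
  if (inherits(x, "encoded_seq")) {
    if (length(x$residues) && max(x$residues) >= length(matrix$alphabet)) {
      stop("encoded sequence has indices outside the matrix alphabet",
        call. = FALSE)
    }
    return(x)
  }
  encode_sequence(x, matrix, id = id)
}
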