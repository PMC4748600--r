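#' Enhanced suffix-array exact-seed index
#'
#' Builds a generalized suffix array with a longest-common-prefix (LCP) array
#' over a set of sequences joined with distinct terminator sentinels. The
#' index answers arbitrary-length exact substring queries; the batch aligner
#' uses it to skip pairs that share no exact-matching seed of a given length.
#' Sentinels never participate in a reported match. Construction is
#' deterministic.
#'
#' @param sequences a list of residue strings or [encode_sequence()] results,
#'   optionally named; names (or integer positions) are the ids accepted by
#'   [longest_shared_seed()].
#' @param matrix matrix whose alphabet is used to encode character input.
#' @return A `seed_index`.
#' @examples
#' idx <- build_seed_index(list(a = "ACGT", b = "CGTA"))
#' longest_shared_seed(idx, "a", "b") # 3 ("CGT")
#' @export
build_seed_index <- function(sequences, matrix = builtin_matrix("BLOSUM62")) {
  if (!is.list(sequences) || length(sequences) == 0L) {
    stop("cannot index an empty sequence list", call. = FALSE)
  }
  matrix <- as_subst_matrix(matrix)
  enc <- lapply(seq_along(sequences), function(i) {
    as_encoded(sequences[[i]], matrix, id = paste0("seq", i))$residues
  })
  esa <- cpp_esa_build(enc)
  structure(
    list(
      sa = esa$sa, lcp = esa$lcp, origin = esa$origin, n = esa$n,
      ids = if (!is.null(names(sequences))) names(sequences)
            else as.character(seq_along(sequences)),
      lengths = vapply(enc, length, integer(1))
    ),
    class = "seed_index"
  )
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %d sequences, %d indexed positions\n",
    length(x$ids), x$n))
  invisible(x)
}

.seed_id <- function(index, id) {
  if (is.numeric(id)) {
    id <- as.integer(id)
    if (id < 1L || id > length(index$ids)) {
      stop(sprintf("sequence id %d not in index (1..%d)", id, length(index$ids)),
        call. = FALSE)
    }
    return(id)
  }
  pos <- match(as.character(id), index$ids)
  if (is.na(pos)) {
    stop(sprintf("unknown sequence id '%s'", id), call. = FALSE)
  }
  pos
}

#' Longest exact seed shared by two indexed sequences
#'
#' Returns the length of the longest exact substring occurring in both
#' sequences (0 if none). A pair passes the seed filter at seed length `k`
#' iff the returned length is at least `k`.
#'
#' @param index a [build_seed_index()] result.
#' @param a,b sequence ids (names given at build time, or integer positions).
#' @return Integer seed length.
#' @export
longest_shared_seed <- function(index, a, b) {
  stopifnot(inherits(index, "seed_index"))
  ia <- .seed_id(index, a)
  ib <- .seed_id(index, b)
  if (ia == ib) return(index$lengths[ia])
  cpp_esa_lcs(index$lcp, index$origin, ia - 1L, ib - 1L)
}
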