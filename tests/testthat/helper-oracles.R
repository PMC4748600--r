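# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package: global scores come from exhaustive
# enumeration of alignment move sequences with run-length gap costing, and
# longest common substrings from a quadratic scan.

toy_dna <- function(match = 2L, mismatch = -1L) {
  sc <- matrix(as.integer(mismatch), 4L, 4L)
  diag(sc) <- as.integer(match)
  subst_matrix(c("A", "C", "G", "T"), sc, "toy-dna")
}

# exhaustive global alignment score: recursion over substitute / delete /
# insert moves, charging open + extend when a gap starts and extend when it
# continues (affine cost by gap-state tracking, not by DP recurrence)
enum_global <- function(q, d, open, extend, mat) {
  qc <- strsplit(toupper(q), "")[[1]]
  dc <- strsplit(toupper(d), "")[[1]]
  m <- length(qc)
  n <- length(dc)
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > m && j > n) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= m && j <= n) {
      rec(i + 1L, j + 1L, score + mat$scores[qc[i], dc[j]], "s")
    }
    if (i <= m) {
      rec(i + 1L, j, score - extend - if (state == "d") 0 else open, "d")
    }
    if (j <= n) {
      rec(i, j + 1L, score - extend - if (state == "i") 0 else open, "i")
    }
  }
  rec(1L, 1L, 0, "none")
  best
}

# semi-global: free end gaps in either sequence — skip a prefix of one
# sequence and a suffix of one sequence, globally align the rest. The
# alignment itself must be non-empty (it ends at an interior table cell), so
# the score can be negative for mutually dissimilar sequences.
enum_semiglobal <- function(q, d, open, extend, mat) {
  m <- nchar(q)
  n <- nchar(d)
  if (m == 0 || n == 0) return(0)
  best <- -Inf
  for (i0 in 0:m) for (j0 in 0:n) {
    if (i0 > 0 && j0 > 0) next
    for (i1 in i0:m) for (j1 in j0:n) {
      if (i1 < m && j1 < n) next     # ends on the last row or column
      if (i1 < 1 || j1 < 1) next     # interior end cell
      if (i1 == i0 && j1 == j0) next # non-empty path
      best <- max(best, enum_global(substr(q, i0 + 1, i1),
        substr(d, j0 + 1, j1), open, extend, mat))
    }
  }
  best
}

# local: best over all substring pairs, floored at zero
enum_local <- function(q, d, open, extend, mat) {
  best <- 0
  for (i0 in 0:nchar(q)) for (i1 in i0:nchar(q)) {
    for (j0 in 0:nchar(d)) for (j1 in j0:nchar(d)) {
      best <- max(best, enum_global(substr(q, i0 + 1, i1),
        substr(d, j0 + 1, j1), open, extend, mat))
    }
  }
  best
}

# quadratic longest-common-substring oracle
lcs_substring <- function(a, b) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  if (!length(ac) || !length(bc)) return(0L)
  prev <- integer(length(bc))
  best <- 0L
  for (i in seq_along(ac)) {
    cur <- integer(length(bc))
    for (j in seq_along(bc)) {
      if (ac[i] == bc[j]) {
        cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# Biostrings score oracle (independent implementation path)
bios_score <- function(cls, q, d, open, extend, mat) {
  type <- switch(cls, nw = "global", sg = "overlap", sw = "local")
  Biostrings::pairwiseAlignment(q, d, type = type,
    substitutionMatrix = mat$scores, gapOpening = open,
    gapExtension = extend, scoreOnly = TRUE)
}

rand_residues <- function(n, alphabet) {
  if (n == 0L) "" else paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

aa20 <- setdiff(builtin_matrix("BLOSUM62")$alphabet, c("B", "Z", "X", "*"))
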