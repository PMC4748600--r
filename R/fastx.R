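#' Read sequences from a FASTA or FASTQ file
#'
#' The format is auto-detected from the first non-blank character (`>` for
#' FASTA, `@` for FASTQ). Multi-line FASTA records are concatenated, FASTQ
#' quality lines are parsed and discarded, and surrounding whitespace is
#' stripped. Identifiers are the first whitespace-delimited token of the
#' header. Parsing is delegated to Biostrings; record-level problems (a FASTQ
#' record without its `+` separator, an empty identifier) are reported with
#' the record number.
#'
#' @param path path to an existing FASTA or FASTQ file.
#' @return A tibble with columns `id` and `seq`, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "GG"), f)
#' read_sequences(f)
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("sequence file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) {
    stop(sprintf("sequence file is empty: %s", path), call. = FALSE)
  }
  first <- substr(trimws(nonblank[1L]), 1L, 1L)
  fmt <- switch(first, ">" = "fasta", "@" = "fastq",
    stop(sprintf(
      "cannot detect format of '%s': first record starts with '%s', not '>' or '@'",
      path, first), call. = FALSE))
  if (fmt == "fastq") .validate_fastq(nonblank)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) {
      stop(sprintf("failed to parse %s file '%s': %s", fmt, path,
        conditionMessage(e)), call. = FALSE)
    })
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop(sprintf("record %d in '%s' has an empty identifier",
      which(!nzchar(ids))[1L], path), call. = FALSE)
  }
  tibble::tibble(id = unname(ids),
    seq = toupper(gsub("\\s", "", unname(as.character(set)))))
}

# minimal structural check so FASTQ errors carry a record number
.validate_fastq <- function(lines) {
  i <- 1L
  rec <- 0L
  n <- length(lines)
  while (i <= n) {
    rec <- rec + 1L
    if (substr(lines[i], 1L, 1L) != "@") {
      stop(sprintf("FASTQ record %d: header does not start with '@'", rec),
        call. = FALSE)
    }
    if (!nzchar(sub("\\s.*$", "", substr(lines[i], 2L, nchar(lines[i]))))) {
      stop(sprintf("FASTQ record %d has an empty identifier", rec),
        call. = FALSE)
    }
    if (i + 2L > n || substr(lines[i + 2L], 1L, 1L) != "+") {
      stop(sprintf("FASTQ record %d: missing '+' separator line", rec),
        call. = FALSE)
    }
    if (i + 3L > n) {
      stop(sprintf("FASTQ record %d: missing quality line", rec),
        call. = FALSE)
    }
    i <- i + 4L
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs a data frame with columns `id` and `seq` (as returned by
#'   [read_sequences()]), or a named character vector.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- tibble::tibble(id = names(seqs), seq = unname(seqs))
  }
  writeLines(paste0(">", seqs$id, "\n", seqs$seq), path, sep = "\n")
  invisible(path)
}
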