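# FASTA input/output.
#
# Readers in this package must accept exactly what tree-building pipelines
# hand around: interleaved or sequential FASTA written on any platform (LF,
# CRLF or lone-CR line endings), with duplicate headers preserved and the
# full header line (not just the first token) kept as the record identity.
# Output is always sequential (one sequence line per record), LF-terminated.

#' Read a FASTA file into a records data frame
#'
#' Accepts interleaved (multi-line) or sequential (single-line) FASTA with
#' LF, CRLF or lone-CR line endings; all three parse to identical records.
#' Each record keeps the full header line (leading `>` and trailing
#' whitespace stripped) and the concatenated sequence with all internal
#' whitespace removed. Record order and duplicate headers are preserved.
#' Content before the first `>` is a fatal format error; a header with no
#' sequence lines is kept (empty sequence) with a warning so concordance
#' reporting can still see it.
#'
#' @param file Path to a FASTA file, or `NULL` when `text` is given.
#' @param text Full FASTA content as a character scalar.
#' @return A data frame with character columns `header` and `sequence`, one
#'   row per record in file order.
#' @examples
#' read_fasta(text = ">A\nACGT\nACGT\n>B\nTTTT\n")
#' @export
read_fasta <- function(file = NULL, text = NULL) {
  text <- normalize_eol(slurp(file, text))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    parse_error("FASTA input is empty")
  }
  if (!startsWith(lines[nonblank[1L]], ">")) {
    parse_error("FASTA format error: content found before the first '>' header")
  }
  hdr_idx <- which(startsWith(lines, ">"))
  headers <- sub("[ \t]+$", "", substring(lines[hdr_idx], 2L))
  if (any(!nzchar(headers))) {
    parse_error("FASTA format error: '>' header line with no name")
  }
  starts <- hdr_idx + 1L
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  sequences <- vapply(seq_along(hdr_idx), function(k) {
    if (starts[k] > ends[k]) return("")
    gsub("[ \t]", "", paste(lines[starts[k]:ends[k]], collapse = ""))
  }, "")
  empty <- !nzchar(sequences)
  if (any(empty)) {
    tipsort_warn(
      sprintf("FASTA record(s) with empty sequence: %s",
              paste(headers[empty], collapse = ", ")),
      "tipsort_empty_sequence"
    )
  }
  data.frame(header = headers, sequence = sequences, stringsAsFactors = FALSE)
}

#' Write records as sequential FASTA
#'
#' Each record becomes one `>`-header line followed by its whole sequence on
#' a single line. Line endings are LF regardless of platform, and sequence
#' bytes are written exactly as stored, so `read_fasta(write_fasta(x))`
#' round-trips to `x`.
#'
#' @param records Data frame with `header` and `sequence` columns, as
#'   returned by [read_fasta()]; must be non-empty.
#' @param file Destination path.
#' @return Invisibly, the destination path.
#' @export
write_fasta <- function(records, file) {
  stopifnot(is.data.frame(records),
            all(c("header", "sequence") %in% names(records)))
  if (nrow(records) == 0L) {
    io_error("refusing to write an empty FASTA file")
  }
  con <- tryCatch(
    file(file, open = "wb"),
    error = function(e) io_error(
      sprintf("cannot open '%s' for writing: %s", file, conditionMessage(e))
    ),
    warning = function(w) io_error(
      sprintf("cannot open '%s' for writing: %s", file, conditionMessage(w))
    )
  )
  on.exit(close(con))
  writeLines(paste0(">", records$header, "\n", records$sequence),
             con, sep = "\n", useBytes = TRUE)
  invisible(file)
}

#' Report duplicated FASTA headers
#'
#' Exact-text duplicates (under full-line identity) with their multiplicity,
#' in order of first appearance. Duplicates are reported for troubleshooting
#' but never dropped: a tree label matching a duplicated header extracts all
#' of its records.
#'
#' @inheritParams write_fasta
#' @return Data frame with columns `header` (character) and `count`
#'   (integer, `>= 2`); zero rows when all headers are unique.
#' @export
find_duplicate_headers <- function(records) {
  counts <- table(records$header)
  dup <- unique(records$header[duplicated(records$header)])
  data.frame(
    header = dup,
    count = as.integer(counts[dup]),
    stringsAsFactors = FALSE
  )
}
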