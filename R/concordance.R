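# Concordance between tree labels and FASTA headers.
#
# Discrepancies between the two inputs (typos, re-exported alignments,
# trimmed headers) are the most common user error in this workflow. The
# report is advisory: everything short of a total mismatch warns and the
# extraction proceeds on the matched intersection. Zero matches is fatal --
# that is a wrong-file pairing, and silently writing empty folders would
# hide it.

#' Cross-check tree labels against FASTA headers
#'
#' Computes the exact set differences between the scheme's labels and the
#' FASTA headers (under the configured matching mode), plus duplicate lists
#' for both files. Missing labels and duplicates are reported as warnings;
#' the caller is expected to continue and extract the matched intersection.
#'
#' @param scheme A [`tipsort_scheme`][build_scheme].
#' @param records FASTA records data frame from [read_fasta()].
#' @param match_mode `"full"` (default) compares tree labels to the full
#'   header line; `"first"` compares to the header's first
#'   whitespace-delimited token.
#' @param translate_underscores Logical; when `TRUE`, underscores are read
#'   as spaces on both sides before comparison (for tree builders that
#'   rewrite spaces, unlike RAxML which preserves FASTA headers verbatim).
#' @return A `tipsort_concordance` list: `tree_labels_missing_in_fasta`,
#'   `fasta_headers_missing_in_tree` (ordered character vectors),
#'   `duplicate_tree_labels`, `duplicate_fasta_headers` (`(label, count)`
#'   data frames), `matched_count` and `n_tree_labels`. Errors (class
#'   `tipsort_zero_match_error`) when no tree label matches any header.
#' @export
check_concordance <- function(scheme, records,
                              match_mode = c("full", "first"),
                              translate_underscores = FALSE) {
  stopifnot(inherits(scheme, "tipsort_scheme"), is.data.frame(records))
  match_mode <- match.arg(match_mode)

  tkey <- match_key(scheme$label, "full", translate_underscores)
  fkey <- match_key(records$header, match_mode, translate_underscores)

  miss_tree <- scheme$label[!(tkey %in% fkey)]
  uniq_hdr <- unique(records$header)
  ukey <- match_key(uniq_hdr, match_mode, translate_underscores)
  miss_fasta <- uniq_hdr[!(ukey %in% tkey)]

  report <- structure(
    list(
      tree_labels_missing_in_fasta = miss_tree,
      fasta_headers_missing_in_tree = miss_fasta,
      duplicate_tree_labels = attr(scheme, "duplicates") %||%
        data.frame(label = character(0), count = integer(0)),
      duplicate_fasta_headers = find_duplicate_headers(records),
      matched_count = sum(tkey %in% fkey),
      n_tree_labels = nrow(scheme)
    ),
    class = "tipsort_concordance"
  )

  if (report$matched_count == 0L) {
    zero_match_error(
      sprintf(paste0(
        "none of the %d tree labels match any FASTA header -- ",
        "are the NEXUS and FASTA files from the same analysis?"
      ), report$n_tree_labels),
      data = report
    )
  }

  if (length(miss_tree) > 0L) {
    tipsort_warn(
      sprintf("%d tree label(s) missing from the FASTA file: %s",
              length(miss_tree), paste(miss_tree, collapse = ", ")),
      "tipsort_missing_label"
    )
  }
  if (length(miss_fasta) > 0L) {
    tipsort_warn(
      sprintf("%d FASTA header(s) absent from the tree: %s",
              length(miss_fasta), paste(miss_fasta, collapse = ", ")),
      "tipsort_extra_header"
    )
  }
  if (nrow(report$duplicate_fasta_headers) > 0L) {
    tipsort_warn(
      sprintf("duplicate FASTA header(s): %s",
              paste(report$duplicate_fasta_headers$header, collapse = ", ")),
      "tipsort_duplicate_header"
    )
  }

  report
}

#' @export
format.tipsort_concordance <- function(x, ...) {
  block <- function(title, v) {
    if (length(v) == 0L) {
      sprintf("%s: none", title)
    } else {
      c(sprintf("%s (%d):", title, length(v)), paste0("  ", v))
    }
  }
  dup_lines <- function(title, df) {
    if (nrow(df) == 0L) {
      sprintf("%s: none", title)
    } else {
      c(sprintf("%s (%d):", title, nrow(df)),
        sprintf("  %s (x%d)", df[[1L]], df$count))
    }
  }
  c(
    "Concordance report",
    sprintf("Tree labels: %d distinct, %d matched in FASTA",
            x$n_tree_labels, x$matched_count),
    block("Tree labels missing in FASTA", x$tree_labels_missing_in_fasta),
    block("FASTA headers missing in tree", x$fasta_headers_missing_in_tree),
    dup_lines("Duplicate tree labels", x$duplicate_tree_labels),
    dup_lines("Duplicate FASTA headers", x$duplicate_fasta_headers)
  )
}

#' @export
print.tipsort_concordance <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
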