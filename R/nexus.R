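# FigTree NEXUS dialect: taxa-block parsing.
#
# When FigTree saves an edited tree it writes a NEXUS file whose taxa block
# carries the per-tip edits as bracketed attribute comments appended to each
# taxlabels entry, e.g.
#
#   begin taxa;
#       dimensions ntax=20;
#       taxlabels
#       'A'[&!color=#ff0000]
#       'C'[&!name="Group1",!color=#ff0000]
#       H
#   ;
#   end;
#
# Only this block is consulted; trees and figtree settings blocks (including
# any per-branch color attributes) are ignored. That keeps the contract
# minimal: tip attributes, not topology, drive the extraction.

#' Parse the taxa block of a FigTree-saved NEXUS file
#'
#' Extracts one [TaxonRecord] row per `taxlabels` entry, in file order,
#' decoding the tip color (normalized to an uppercase hex code, see
#' [normalize_color()]) and the user annotation stored under `annotation_key`.
#' Entries without an attribute comment yield `NA` for both. Parsing is
#' insensitive to line-ending convention and to whitespace layout between
#' entries. Malformed attribute comments produce a warning and the affected
#' tip keeps its label with absent attributes; a missing taxa block or
#' missing `taxlabels` statement is a fatal parse error.
#'
#' @param file Path to a NEXUS file, or `NULL` when `text` is given.
#' @param text Full NEXUS content as a character scalar (alternative to
#'   `file`).
#' @param annotation_key Attribute key (case-insensitive) under which FigTree
#'   stored the user's annotation; FigTree's display-name attribute `"!name"`
#'   by default.
#' @return A data frame with character columns `label`, `color`, `annotation`
#'   (the latter two `NA` when absent), one row per taxlabels entry in file
#'   order.
#' @examples
#' nex <- "#NEXUS\nbegin taxa;\n taxlabels\n 'A'[&!color=#ff0000]\n 'H'\n;\nend;"
#' parse_figtree_nexus(text = nex)
#' @seealso [parse_taxlabel_entry()] for the single-entry unit,
#'   [build_scheme()] for the next pipeline stage.
#' @export
parse_figtree_nexus <- function(file = NULL, text = NULL,
                                annotation_key = "!name") {
  text <- normalize_eol(slurp(file, text))

  beg <- regexpr("begin\\s+taxa\\s*;", text, ignore.case = TRUE, perl = TRUE)
  if (beg == -1L) {
    parse_error(paste0(
      "no taxa block ('begin taxa;') found in NEXUS input -- ",
      "is this a FigTree-saved NEXUS file?"
    ))
  }
  rest <- substring(text, beg + attr(beg, "match.length"))
  end <- regexpr("\\bend\\s*;", rest, ignore.case = TRUE, perl = TRUE)
  block <- if (end == -1L) rest else substring(rest, 1L, end - 1L)

  tl <- regexpr("\\btaxlabels\\b", block, ignore.case = TRUE, perl = TRUE)
  if (tl == -1L) {
    parse_error("no 'taxlabels' statement found in the taxa block")
  }
  body <- substring(block, tl + attr(tl, "match.length"))

  entries <- split_taxlabel_entries(body)
  if (length(entries) == 0L) {
    parse_error("the taxlabels statement lists no taxa")
  }
  recs <- lapply(entries, parse_taxlabel_entry, annotation_key = annotation_key)
  data.frame(
    label = vapply(recs, `[[`, "", "label"),
    color = vapply(recs, `[[`, "", "color"),
    annotation = vapply(recs, `[[`, "", "annotation"),
    stringsAsFactors = FALSE
  )
}

#' Parse one taxlabels entry into a taxon record
#'
#' A single entry is a label -- bare, or single-quoted with doubled quotes
#' (`''`) escaping an embedded quote -- optionally followed immediately by a
#' FigTree attribute comment `[&key=value,...]`. Attribute keys are matched
#' case-insensitively; values may be bare, double-quoted, or `#`-prefixed
#' colors; unknown keys are ignored. An unbalanced quote or bracket issues a
#' malformed-entry warning: the label is recovered on best effort and the
#' attributes are dropped.
#'
#' @param entry One raw taxlabels token (label plus optional trailing
#'   comment) as character scalar.
#' @inheritParams parse_figtree_nexus
#' @return A list with elements `label`, `color`, `annotation` (attributes
#'   `NA_character_` when absent).
#' @examples
#' parse_taxlabel_entry("'Uncultured organism X12'[&!color=#0000ff]")
#' parse_taxlabel_entry("'it''s'")
#' @export
parse_taxlabel_entry <- function(entry, annotation_key = "!name") {
  stopifnot(is.character(entry), length(entry) == 1L)
  entry <- trimws(entry)
  rec <- list(label = NA_character_, color = NA_character_,
              annotation = NA_character_)

  if (startsWith(entry, "'")) {
    chars <- strsplit(entry, "", fixed = TRUE)[[1]]
    n <- length(chars)
    i <- 2L
    closed <- FALSE
    while (i <= n) {
      if (chars[i] == "'") {
        if (i < n && chars[i + 1L] == "'") {
          i <- i + 2L
        } else {
          closed <- TRUE
          break
        }
      } else {
        i <- i + 1L
      }
    }
    inner <- if (i >= 2L && i - 1L >= 2L) {
      substring(entry, 2L, i - 1L)
    } else {
      ""
    }
    rec$label <- gsub("''", "'", inner, fixed = TRUE)
    if (!closed) {
      tipsort_warn(
        sprintf("unbalanced quote in taxlabels entry %s; attributes dropped",
                entry),
        "tipsort_malformed_entry"
      )
      return(rec)
    }
    remainder <- substring(entry, i + 1L)
  } else {
    br <- regexpr("[", entry, fixed = TRUE)
    if (br == -1L) {
      rec$label <- entry
      remainder <- ""
    } else {
      rec$label <- substring(entry, 1L, br - 1L)
      remainder <- substring(entry, br)
    }
  }

  if (!nzchar(rec$label)) {
    tipsort_warn(
      sprintf("empty label in taxlabels entry %s", entry),
      "tipsort_malformed_entry"
    )
  }

  remainder <- trimws(remainder)
  if (nzchar(remainder)) {
    attrs <- parse_attr_comment(remainder, annotation_key)
    rec$color <- attrs$color
    rec$annotation <- attrs$annotation
  }
  rec
}

# Split the text following `taxlabels` into raw entry strings, stopping at
# the terminating (unquoted, unbracketed) semicolon. A bracketed chunk glued
# to a label is part of that entry; one floating on its own is a plain NEXUS
# comment and is skipped.
split_taxlabel_entries <- function(body) {
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_ws <- chars %in% c(" ", "\t", "\n")
  entries <- character(0)
  i <- 1L
  while (i <= n) {
    if (is_ws[i]) {
      i <- i + 1L
      next
    }
    ch <- chars[i]
    if (ch == ";") break
    if (ch == "[") {
      i <- skip_bracket(chars, i)
      next
    }
    start <- i
    if (ch == "'") {
      i <- i + 1L
      repeat {
        if (i > n) {
          tipsort_warn("unterminated quoted label at end of taxlabels",
                       "tipsort_malformed_entry")
          break
        }
        if (chars[i] == "'") {
          if (i < n && chars[i + 1L] == "'") {
            i <- i + 2L
          } else {
            i <- i + 1L
            break
          }
        } else {
          i <- i + 1L
        }
      }
    } else {
      while (i <= n && !is_ws[i] &&
             !(chars[i] %in% c(";", "[", "'"))) {
        i <- i + 1L
      }
    }
    if (i <= n && chars[i] == "[") {
      i <- skip_bracket(chars, i)
    }
    entries <- c(entries, substr(body, start, i - 1L))
  }
  entries
}

# Advance past a bracketed comment starting at chars[i] == "[". Tracks
# nesting depth and double-quoted strings (a ']' inside quotes does not
# close). Returns the index just past the closing bracket; warns and
# consumes to end of input when unterminated.
skip_bracket <- function(chars, i) {
  n <- length(chars)
  depth <- 0L
  in_quote <- FALSE
  while (i <= n) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == '"') in_quote <- FALSE
    } else if (ch == '"') {
      in_quote <- TRUE
    } else if (ch == "[") {
      depth <- depth + 1L
    } else if (ch == "]") {
      depth <- depth - 1L
      if (depth == 0L) return(i + 1L)
    }
    i <- i + 1L
  }
  tipsort_warn("unterminated '[' comment in taxlabels",
               "tipsort_malformed_entry")
  n + 1L
}

# Decode a FigTree attribute comment "[&k1=v1,k2=v2,...]" into the color and
# annotation attributes. Any anomaly warns and leaves the attribute absent.
parse_attr_comment <- function(comment, annotation_key) {
  out <- list(color = NA_character_, annotation = NA_character_)
  if (!startsWith(comment, "[") || !endsWith(comment, "]")) {
    tipsort_warn(
      sprintf("malformed attribute comment %s; attributes dropped", comment),
      "tipsort_malformed_entry"
    )
    return(out)
  }
  inner <- substring(comment, 2L, nchar(comment) - 1L)
  inner <- sub("^\\s*&", "", inner)
  if (!nzchar(trimws(inner))) return(out)

  for (pair in split_outside_quotes(inner, ",")) {
    pair <- trimws(pair)
    if (!nzchar(pair)) next
    eq <- regexpr("=", pair, fixed = TRUE)
    if (eq == -1L) {
      tipsort_warn(
        sprintf("attribute '%s' has no '=value'; ignored", pair),
        "tipsort_malformed_entry"
      )
      next
    }
    key <- trimws(substring(pair, 1L, eq - 1L))
    val <- trimws(substring(pair, eq + 1L))
    if (nchar(val) >= 2L && startsWith(val, '"') && endsWith(val, '"')) {
      val <- substring(val, 2L, nchar(val) - 1L)
    }
    if (tolower(key) == "!color") {
      out$color <- normalize_color(val)
    } else if (tolower(key) == tolower(annotation_key)) {
      if (nzchar(val)) {
        out$annotation <- val
      } else {
        tipsort_warn("empty annotation value; treated as absent",
                     "tipsort_malformed_entry")
      }
    }
    # unknown keys: ignored by contract
  }
  out
}

# strsplit on `sep` occurring outside double-quoted spans.
split_outside_quotes <- function(x, sep) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  in_quote <- FALSE
  cut <- logical(length(chars))
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == '"') {
      in_quote <- !in_quote
    } else if (ch == sep && !in_quote) {
      cut[i] <- TRUE
    }
  }
  if (!any(cut)) return(x)
  idx <- c(0L, which(cut), length(chars) + 1L)
  vapply(seq_len(length(idx) - 1L), function(k) {
    lo <- idx[k] + 1L
    hi <- idx[k + 1L] - 1L
    if (lo > hi) "" else substr(x, lo, hi)
  }, "")
}
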