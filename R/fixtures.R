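# Synthetic fixture generator.
#
# Every test in this package runs against generated data: a matched
# (Newick, FigTree-style NEXUS, FASTA) triple with a known ground-truth
# selection scheme and concordance report. The NEXUS writer deliberately
# varies quoting style and color encoding (hex vs signed 32-bit ARGB
# decimal) from a seeded RNG so the parser is exercised across the dialect,
# and defects (duplicates, missing/extra records, malformed comments) can be
# injected with the expected reports computed by bookkeeping, not by the
# code under test.

#' Describe a synthetic fixture
#'
#' Captures everything [generate_fixture()] needs: taxon count, the color
#' and annotation pools with their assignment probabilities (or explicit
#' per-taxon assignments), sequence length, RNG seed, and the set of
#' injected defects. The same spec and seed always produce byte-identical
#' fixture files.
#'
#' @param n_taxa Number of taxa (`>= 2`). Default labels are `A`..`Z` for up
#'   to 26 taxa, `taxon_0001`-style beyond.
#' @param colors Character vector of 6-hex-digit uppercase colors available
#'   for assignment (empty: no tip is colored).
#' @param annotations Character vector of annotation names available.
#' @param color_prob Probability that a taxon receives a color (drawn
#'   uniformly from `colors`); ignored when `color_assign` is given.
#' @param annot_prob Likewise for annotations.
#' @param color_assign Optional explicit character vector, length `n_taxa`,
#'   of per-taxon colors (`NA` for none); overrides random assignment.
#' @param annot_assign Optional explicit per-taxon annotations (`NA` for
#'   none).
#' @param labels Optional explicit taxon labels (unique, length `n_taxa`).
#' @param seq_length Length of the random A/C/G/T sequences.
#' @param seed Integer RNG seed.
#' @param defects Character subset of `"duplicate_header"`,
#'   `"missing_record"`, `"extra_record"`, `"malformed_comment"`,
#'   `"conflicting_duplicate_label"`.
#' @param layout FASTA layout: `"auto"` (random per record),
#'   `"sequential"`, or `"interleaved"` (wrapped at 60 columns).
#' @param eol Line-ending convention for both emitted files.
#' @return A `tipsort_fixture_spec` list.
#' @export
fixture_spec <- function(n_taxa,
                         colors = character(0),
                         annotations = character(0),
                         color_prob = 0.7,
                         annot_prob = 0.5,
                         color_assign = NULL,
                         annot_assign = NULL,
                         labels = NULL,
                         seq_length = 60L,
                         seed = 1L,
                         defects = character(0),
                         layout = c("auto", "sequential", "interleaved"),
                         eol = c("lf", "crlf", "cr")) {
  known <- c("duplicate_header", "missing_record", "extra_record",
             "malformed_comment", "conflicting_duplicate_label")
  if (n_taxa < 2L) stop("fixtures need n_taxa >= 2")
  if (length(bad <- setdiff(defects, known)) > 0L) {
    stop("unknown defect(s): ", paste(bad, collapse = ", "))
  }
  if (length(colors) > 0L && any(!grepl("^[0-9A-F]{6}$", colors))) {
    stop("colors must be 6-hex-digit uppercase strings")
  }
  targeted <- setdiff(defects, "extra_record")
  if (length(targeted) > n_taxa) {
    stop("more defect targets than taxa")
  }
  if (!is.null(labels) && (length(labels) != n_taxa || anyDuplicated(labels))) {
    stop("labels must be unique and of length n_taxa")
  }
  for (nm in c("color_assign", "annot_assign")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n_taxa) {
      stop(nm, " must have length n_taxa")
    }
  }
  structure(
    list(n_taxa = as.integer(n_taxa), colors = colors,
         annotations = annotations, color_prob = color_prob,
         annot_prob = annot_prob, color_assign = color_assign,
         annot_assign = annot_assign, labels = labels,
         seq_length = as.integer(seq_length), seed = as.integer(seed),
         defects = defects, layout = match.arg(layout),
         eol = match.arg(eol)),
    class = "tipsort_fixture_spec"
  )
}

#' Generate a matched synthetic NEXUS + FASTA fixture
#'
#' Emits a FigTree-style NEXUS file (taxa block with attribute comments,
#' trees block with a random bifurcating tree, figtree settings stub) and
#' the matching FASTA, together with the ground-truth selection scheme and
#' concordance report implied by the spec and its injected defects. Quoting
#' styles and color encodings alternate at random under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory: when given, `fixture.nex`, `fixture.fas`
#'   and `fixture.nwk` are written there and their paths returned.
#' @return A list: `nexus`, `fasta`, `newick` (text), `scheme` (expected
#'   [`tipsort_scheme`][build_scheme]), `concordance` (expected report
#'   fields), `spec`, and `paths` when `dir` was given.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "tipsort_fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_taxa
    labels <- spec$labels %||% (
      if (n <= 26L) LETTERS[seq_len(n)] else sprintf("taxon_%04d", seq_len(n))
    )

    color <- spec$color_assign %||% {
      if (length(spec$colors) == 0L) rep(NA_character_, n)
      else ifelse(stats::runif(n) < spec$color_prob,
                  sample(spec$colors, n, replace = TRUE), NA_character_)
    }
    annotation <- spec$annot_assign %||% {
      if (length(spec$annotations) == 0L) rep(NA_character_, n)
      else ifelse(stats::runif(n) < spec$annot_prob,
                  sample(spec$annotations, n, replace = TRUE), NA_character_)
    }

    # assign defect targets to distinct taxa
    targeted <- intersect(
      c("missing_record", "duplicate_header", "malformed_comment",
        "conflicting_duplicate_label"),
      spec$defects
    )
    target <- stats::setNames(
      sample(n, length(targeted)),
      targeted
    )

    expected_color <- color
    expected_annot <- annotation
    if ("malformed_comment" %in% targeted) {
      i <- target[["malformed_comment"]]
      expected_color[i] <- NA_character_
      expected_annot[i] <- NA_character_
    }

    newick <- generate_random_tree(n, labels = labels)

    # --- taxa block entries ---
    entry <- character(n)
    for (i in seq_len(n)) {
      lab <- nexus_quote_label(labels[i],
                               force = stats::runif(1) < 0.5)
      if ("malformed_comment" %in% targeted &&
          i == target[["malformed_comment"]]) {
        entry[i] <- paste0(lab, "[&!color=notacolor]")
        next
      }
      entry[i] <- paste0(lab,
                         render_attr_comment(color[i], annotation[i]))
    }
    dup_tree <- data.frame(label = character(0), count = integer(0),
                           stringsAsFactors = FALSE)
    if ("conflicting_duplicate_label" %in% targeted) {
      i <- target[["conflicting_duplicate_label"]]
      other <- setdiff(c("123456", "654321"), color[i])[1L]
      entry <- c(entry, paste0(nexus_quote_label(labels[i], force = TRUE),
                               render_attr_comment(other, NA_character_)))
      dup_tree <- data.frame(label = labels[i], count = 2L,
                             stringsAsFactors = FALSE)
    }

    nexus <- paste0(
      "#NEXUS\n",
      sprintf("[! synthetic fixture generated by tipsort (Mersenne-Twister RNG, seed %d) ]\n",
              spec$seed),
      "begin taxa;\n",
      sprintf("\tdimensions ntax=%d;\n", n),
      "\ttaxlabels\n",
      paste0("\t", entry, "\n", collapse = ""),
      ";\nend;\n\n",
      "begin trees;\n",
      sprintf("\ttree tree_1 = [&R] %s\n", newick),
      "end;\n\n",
      "begin figtree;\n\tset appearance.branchLineWidth=1.0;\nend;\n"
    )

    # --- FASTA ---
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), spec$seq_length, replace = TRUE),
            collapse = "")
    }, "")
    fasta_headers <- labels
    fasta_seqs <- seqs

    missing_label <- character(0)
    if ("missing_record" %in% targeted) {
      i <- target[["missing_record"]]
      missing_label <- labels[i]
      keep <- fasta_headers != labels[i]
      fasta_headers <- fasta_headers[keep]
      fasta_seqs <- fasta_seqs[keep]
    }
    dup_fasta <- data.frame(header = character(0), count = integer(0),
                            stringsAsFactors = FALSE)
    if ("duplicate_header" %in% targeted) {
      i <- target[["duplicate_header"]]
      fasta_headers <- c(fasta_headers, labels[i])
      fasta_seqs <- c(fasta_seqs, seqs[i])
      dup_fasta <- data.frame(header = labels[i], count = 2L,
                              stringsAsFactors = FALSE)
    }
    extra_headers <- character(0)
    if ("extra_record" %in% spec$defects) {
      extra_headers <- sprintf("extra_record_%d", 1:5)
      fasta_headers <- c(fasta_headers, extra_headers)
      fasta_seqs <- c(fasta_seqs, vapply(1:5, function(i) {
        paste(sample(c("A", "C", "G", "T"), spec$seq_length, replace = TRUE),
              collapse = "")
      }, ""))
    }

    wrap <- switch(spec$layout,
      sequential = rep(FALSE, length(fasta_headers)),
      interleaved = rep(TRUE, length(fasta_headers)),
      auto = stats::runif(length(fasta_headers)) < 0.5
    )
    body <- vapply(seq_along(fasta_headers), function(k) {
      s <- fasta_seqs[k]
      if (wrap[k] && nchar(s) > 60L) {
        s <- paste(regmatches(s, gregexpr(".{1,60}", s))[[1]],
                   collapse = "\n")
      }
      paste0(">", fasta_headers[k], "\n", s, "\n")
    }, "")
    fasta <- paste(body, collapse = "")

    if (spec$eol == "crlf") {
      nexus <- gsub("\n", "\r\n", nexus, fixed = TRUE)
      fasta <- gsub("\n", "\r\n", fasta, fixed = TRUE)
    } else if (spec$eol == "cr") {
      nexus <- gsub("\n", "\r", nexus, fixed = TRUE)
      fasta <- gsub("\n", "\r", fasta, fixed = TRUE)
    }

    scheme <- data.frame(label = labels, color = expected_color,
                         annotation = expected_annot,
                         stringsAsFactors = FALSE)
    attr(scheme, "duplicates") <- dup_tree
    class(scheme) <- c("tipsort_scheme", "data.frame")

    concordance <- list(
      tree_labels_missing_in_fasta = missing_label,
      fasta_headers_missing_in_tree = extra_headers,
      duplicate_tree_labels = dup_tree,
      duplicate_fasta_headers = dup_fasta,
      matched_count = n - length(missing_label),
      n_tree_labels = n
    )

    out <- list(nexus = nexus, fasta = fasta, newick = newick,
                scheme = scheme, concordance = concordance, spec = spec)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- file.path(dir, c("fixture.nex", "fixture.fas", "fixture.nwk"))
      writeChar(nexus, paths[1L], eos = NULL)
      writeChar(fasta, paths[2L], eos = NULL)
      writeChar(paste0(newick, "\n"), paths[3L], eos = NULL)
      out$paths <- stats::setNames(paths, c("nexus", "fasta", "newick"))
    }
    out
  })
}

#' Generate a random bifurcating tree
#'
#' Builds a Newick string by sequential random joins of the leaf set; the
#' topology only serves to make fixtures resemble real FigTree sessions
#' (tip attributes, not topology, drive the extraction). Branch lengths are
#' uniform random draws without biological meaning.
#'
#' @param n_taxa Number of leaves (`>= 2`).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (as inside [generate_fixture()]).
#' @param labels Optional unique leaf labels; same defaults as
#'   [fixture_spec()].
#' @return A Newick string terminated by `;`.
#' @export
generate_random_tree <- function(n_taxa, seed = NULL, labels = NULL) {
  if (n_taxa < 2L) stop("a tree needs at least 2 leaves")
  gen <- function() {
    labels <- labels %||% (
      if (n_taxa <= 26L) LETTERS[seq_len(n_taxa)]
      else sprintf("taxon_%04d", seq_len(n_taxa))
    )
    stopifnot(length(labels) == n_taxa, !anyDuplicated(labels))
    nodes <- vapply(labels, newick_quote_label, "")
    while (length(nodes) > 1L) {
      i <- sample(length(nodes), 2L)
      joined <- sprintf("(%s:%.3f,%s:%.3f)",
                        nodes[i[1L]], stats::runif(1),
                        nodes[i[2L]], stats::runif(1))
      nodes <- c(nodes[-i], joined)
    }
    paste0(nodes, ";")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Quote a label NEXUS-style when needed (or when forced, to vary the
# dialect); embedded single quotes double.
nexus_quote_label <- function(label, force = FALSE) {
  if (force || grepl("[^A-Za-z0-9_.]", label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}

newick_quote_label <- function(label) {
  if (grepl("[^A-Za-z0-9_.-]", label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}

# Render the FigTree attribute comment for one tip, alternating encodings:
# colors as lower/upper hex or signed 32-bit ARGB decimal, annotations
# quoted or bare, key order shuffled, with an occasional unknown key.
render_attr_comment <- function(color, annotation) {
  parts <- character(0)
  if (!is.na(color)) {
    enc <- sample(c("hexlower", "hexupper", "decimal"), 1L)
    val <- switch(enc,
      hexlower = paste0("#", tolower(color)),
      hexupper = paste0("#", color),
      decimal = {
        v <- 0xFF000000 + strtoi(color, base = 16L)
        format(if (v >= 2^31) v - 2^32 else v, scientific = FALSE)
      }
    )
    parts <- c(parts, paste0("!color=", val))
  }
  if (!is.na(annotation)) {
    val <- if (stats::runif(1) < 0.5 || grepl("[ ,\"=]", annotation)) {
      paste0('"', annotation, '"')
    } else {
      annotation
    }
    parts <- c(parts, paste0("!name=", val))
  }
  if (length(parts) == 0L) return("")
  if (length(parts) > 1L) parts <- sample(parts)
  if (stats::runif(1) < 0.1) {
    parts <- c(parts, '!highlight="false"')
  }
  paste0("[&", paste(parts, collapse = ","), "]")
}
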