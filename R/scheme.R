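# Selection scheme: the label -> (color?, annotation?) mapping recovered
# from the tree, and its deconstruction into the three output families.
#
# The deconstruction mirrors how the edited tree design is meant to be
# consumed: one subset per color (plus NOCOLOR for the uncolored remainder),
# one per annotation (plus NONAME), and -- when both attribute kinds are in
# use -- the combined refinement, so nested designs (one annotation spanning
# several colors, or one color spanning several annotations) land both the
# enclosing group and each nested subgroup in separate files.

#' Build a selection scheme from parsed taxon records
#'
#' Collapses the taxa table to one entry per label (first occurrence wins on
#' duplicates, with a warning; the duplicates are remembered for concordance
#' reporting) and classes it as a `tipsort_scheme`.
#'
#' @param taxa Data frame with columns `label`, `color`, `annotation`, as
#'   returned by [parse_figtree_nexus()].
#' @return A `tipsort_scheme`: the deduplicated data frame, with a
#'   `duplicates` attribute holding a `(label, count)` data frame of
#'   collapsed duplicates.
#' @export
build_scheme <- function(taxa) {
  stopifnot(is.data.frame(taxa),
            all(c("label", "color", "annotation") %in% names(taxa)))
  if (nrow(taxa) == 0L) {
    parse_error("cannot build a selection scheme from an empty taxa list")
  }
  dup <- duplicated(taxa$label)
  dup_labels <- unique(taxa$label[dup])
  if (length(dup_labels) > 0L) {
    tipsort_warn(
      sprintf("duplicate tree label(s) collapsed to first occurrence: %s",
              paste(dup_labels, collapse = ", ")),
      "tipsort_duplicate_label"
    )
  }
  counts <- table(taxa$label)
  scheme <- taxa[!dup, , drop = FALSE]
  rownames(scheme) <- NULL
  attr(scheme, "duplicates") <- data.frame(
    label = dup_labels,
    count = as.integer(counts[dup_labels]),
    stringsAsFactors = FALSE
  )
  class(scheme) <- c("tipsort_scheme", "data.frame")
  scheme
}

#' @export
print.tipsort_scheme <- function(x, ...) {
  n_col <- sum(!is.na(x$color))
  n_ann <- sum(!is.na(x$annotation))
  cat(sprintf(
    "Selection scheme: %d taxa (%d colored across %d colors, %d annotated across %d annotations)\n",
    nrow(x), n_col, length(unique(x$color[!is.na(x$color)])),
    n_ann, length(unique(x$annotation[!is.na(x$annotation)]))
  ))
  invisible(x)
}

#' Deconstruct a selection scheme into COLOR / ANNOT / COMBO groups
#'
#' Produces the extraction plan:
#' * `color_groups` -- one group per distinct hex color, in order of first
#'   appearance, plus a `NOCOLOR` group holding the uncolored labels
#'   (emitted only when at least one color is in use: with no colors at all
#'   a NOCOLOR file would just duplicate the input).
#' * `annot_groups` -- likewise per annotation, with a `NONAME` complement.
#' * `combo_groups` -- only when the scheme uses at least one color *and*
#'   one annotation: one group per observed (annotation-or-`NONAME`,
#'   color-or-`NOCOLOR`) pair. The doubly-absent (`NONAME`, `NOCOLOR`) pair
#'   is emitted only when such labels coexist with at least one
#'   fully-attributed label; `combo_strict = TRUE` restricts COMBO to
#'   fully-attributed pairs.
#'
#' Group order and within-group label order follow first appearance in the
#' taxa block, so identical schemes always yield identical plans.
#'
#' @param scheme A [`tipsort_scheme`][build_scheme].
#' @param combo_strict Logical; drop COMBO groups with a placeholder
#'   (`NONAME`/`NOCOLOR`) component.
#' @return A `tipsort_plan`: list with `color_groups` and `annot_groups`
#'   (named lists of label vectors) and `combo_groups` (named list of
#'   `list(annotation, color, labels)`). A scheme with no colors and no
#'   annotations yields an empty plan with a nothing-selected warning.
#' @export
deconstruct <- function(scheme, combo_strict = FALSE) {
  stopifnot(inherits(scheme, "tipsort_scheme"))
  lab <- scheme$label
  col <- scheme$color
  ann <- scheme$annotation
  has_col <- !is.na(col)
  has_ann <- !is.na(ann)

  plan <- structure(
    list(color_groups = list(), annot_groups = list(), combo_groups = list()),
    class = "tipsort_plan"
  )

  if (!any(has_col) && !any(has_ann)) {
    tipsort_warn(
      "the tree carries no color or annotation edits; nothing to extract",
      "tipsort_nothing_selected"
    )
    return(plan)
  }

  # group keys ordered by first appearance in the scheme; the NOCOLOR/NONAME
  # complement takes the position of its first member like any other key
  if (any(has_col)) {
    ckey <- ifelse(has_col, col, "NOCOLOR")
    for (h in unique(ckey)) {
      plan$color_groups[[h]] <- lab[ckey == h]
    }
  }

  if (any(has_ann)) {
    akey <- ifelse(has_ann, ann, "NONAME")
    for (a in unique(akey)) {
      plan$annot_groups[[a]] <- lab[akey == a]
    }
  }

  if (any(has_col) && any(has_ann)) {
    ckey <- ifelse(has_col, col, "NOCOLOR")
    akey <- ifelse(has_ann, ann, "NONAME")
    # "\r" cannot occur in parsed values, so it is a safe pair separator
    pair <- paste(akey, ckey, sep = "\r")
    any_full <- any(has_col & has_ann)
    for (p in unique(pair)) {
      idx <- pair == p
      a <- akey[idx][1L]
      h <- ckey[idx][1L]
      placeholder <- (a == "NONAME") || (h == "NOCOLOR")
      if (combo_strict && placeholder) next
      if (a == "NONAME" && h == "NOCOLOR" && !any_full) next
      plan$combo_groups[[paste0(a, "_", h)]] <-
        list(annotation = a, color = h, labels = lab[idx])
    }
  }

  plan
}

#' @export
print.tipsort_plan <- function(x, ...) {
  fam <- function(groups) {
    if (length(groups) == 0L) return("none")
    sizes <- vapply(groups, function(g) {
      length(if (is.list(g)) g$labels else g)
    }, 0L)
    paste0(length(groups), " group(s): ",
           paste(sprintf("%s (%d)", names(groups), sizes), collapse = ", "))
  }
  cat("Extraction plan\n")
  cat("  COLOR: ", fam(x$color_groups), "\n", sep = "")
  cat("  ANNOT: ", fam(x$annot_groups), "\n", sep = "")
  cat("  COMBO: ", fam(x$combo_groups), "\n", sep = "")
  invisible(x)
}
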