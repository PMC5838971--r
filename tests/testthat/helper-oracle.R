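# Brute-force bucketing oracle for deconstruct(): walks labels one by one,
# appending each to its (color), (annotation) and (annotation, color)
# buckets, then applies the emission rules. Deliberately written as a plain
# per-label loop, independent of the vectorized implementation it checks.
oracle_plan <- function(scheme, combo_strict = FALSE) {
  has_col <- any(!is.na(scheme$color))
  has_ann <- any(!is.na(scheme$annotation))
  any_full <- any(!is.na(scheme$color) & !is.na(scheme$annotation))
  cg <- list()
  ag <- list()
  xg <- list()
  for (i in seq_len(nrow(scheme))) {
    l <- scheme$label[i]
    co <- scheme$color[i]
    an <- scheme$annotation[i]
    if (has_col) {
      k <- if (is.na(co)) "NOCOLOR" else co
      cg[[k]] <- c(cg[[k]], l)
    }
    if (has_ann) {
      k <- if (is.na(an)) "NONAME" else an
      ag[[k]] <- c(ag[[k]], l)
    }
    if (has_col && has_ann) {
      a <- if (is.na(an)) "NONAME" else an
      h <- if (is.na(co)) "NOCOLOR" else co
      k <- paste0(a, "_", h)
      if (is.null(xg[[k]])) {
        xg[[k]] <- list(annotation = a, color = h, labels = character(0))
      }
      xg[[k]]$labels <- c(xg[[k]]$labels, l)
    }
  }
  # NOCOLOR/NONAME buckets were appended in label order but keyed on first
  # appearance like every other bucket, so order already matches.
  keep <- vapply(xg, function(g) {
    if (combo_strict && (g$annotation == "NONAME" || g$color == "NOCOLOR")) {
      return(FALSE)
    }
    if (g$annotation == "NONAME" && g$color == "NOCOLOR" && !any_full) {
      return(FALSE)
    }
    TRUE
  }, TRUE)
  canon <- function(x) if (length(x) == 0L) list() else x
  list(color_groups = canon(cg), annot_groups = canon(ag),
       combo_groups = canon(xg[keep]))
}

# Random scheme constructed directly (not via the parser) for property tests.
random_scheme <- function(n = 50,
                          colors = c("FF0000", "00FF00", "0000FF", "AB12CD"),
                          annots = c("Group1", "Group2", "Group3"),
                          p_col = 0.6, p_ann = 0.5) {
  labels <- sprintf("tip_%03d", seq_len(n))
  color <- ifelse(stats::runif(n) < p_col,
                  sample(colors, n, replace = TRUE), NA_character_)
  annotation <- ifelse(stats::runif(n) < p_ann,
                       sample(annots, n, replace = TRUE), NA_character_)
  s <- data.frame(label = labels, color = color, annotation = annotation,
                  stringsAsFactors = FALSE)
  attr(s, "duplicates") <- data.frame(label = character(0),
                                      count = integer(0),
                                      stringsAsFactors = FALSE)
  class(s) <- c("tipsort_scheme", "data.frame")
  s
}

plan_as_list <- function(plan) {
  canon <- function(x) if (length(x) == 0L) list() else x
  list(color_groups = canon(plan$color_groups),
       annot_groups = canon(plan$annot_groups),
       combo_groups = canon(plan$combo_groups))
}
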