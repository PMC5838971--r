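scheme_of <- function(label, color = NA, annotation = NA) {
  s <- data.frame(label = label,
                  color = rep_len(color, length(label)),
                  annotation = rep_len(annotation, length(label)),
                  stringsAsFactors = FALSE)
  attr(s, "duplicates") <- data.frame(label = character(0), count = integer(0),
                                      stringsAsFactors = FALSE)
  class(s) <- c("tipsort_scheme", "data.frame")
  s
}

test_that("duplicate labels collapse to the first occurrence with a warning", {
  taxa <- data.frame(
    label = c("A", "B", "A"),
    color = c("FF0000", NA, "00FF00"),
    annotation = c(NA, NA, NA),
    stringsAsFactors = FALSE
  )
  expect_warning(s <- build_scheme(taxa), class = "tipsort_duplicate_label")
  expect_identical(nrow(s), 2L)
  expect_identical(s$color[s$label == "A"], "FF0000")  # first color wins
  expect_identical(attr(s, "duplicates"),
                   data.frame(label = "A", count = 2L,
                              stringsAsFactors = FALSE))
  expect_error(build_scheme(taxa[0, ]), class = "tipsort_parse_error")
})

test_that("a monochromatic scheme deconstructs to the colored group plus NOCOLOR", {
  s <- scheme_of(LETTERS[1:20],
                 color = ifelse(LETTERS[1:20] %in% c("H", "I"),
                                NA, "FF0000"))
  plan <- deconstruct(s)
  expect_named(plan$color_groups, c("FF0000", "NOCOLOR"))
  expect_length(plan$color_groups$FF0000, 18L)
  expect_identical(plan$color_groups$NOCOLOR, c("H", "I"))
  expect_length(plan$annot_groups, 0L)
  expect_length(plan$combo_groups, 0L)
})

test_that("nesting by annotation keeps the shared color whole and splits the annotations", {
  # Group2 and Group3 both green; two further taxa untouched
  s <- scheme_of(LETTERS[1:8],
                 color = c(rep("00FF00", 6), NA, NA),
                 annotation = c(rep("Group2", 3), rep("Group3", 3), NA, NA))
  plan <- deconstruct(s)
  expect_identical(plan$color_groups$`00FF00`, LETTERS[1:6])
  expect_identical(plan$annot_groups$Group2, LETTERS[1:3])
  expect_identical(plan$annot_groups$Group3, LETTERS[4:6])
  expect_identical(plan$annot_groups$NONAME, c("G", "H"))
  combos <- names(plan$combo_groups)
  expect_setequal(combos, c("Group2_00FF00", "Group3_00FF00",
                            "NONAME_NOCOLOR"))
})

test_that("nesting by color keeps the shared annotation whole and splits the colors", {
  s <- scheme_of(LETTERS[1:9],
                 color = c(rep("A52A2A", 2), rep("FF0000", 3),
                           rep("FFC0CB", 2), NA, NA),
                 annotation = c(rep("Group4", 7), NA, NA))
  plan <- deconstruct(s)
  expect_identical(plan$annot_groups$Group4, LETTERS[1:7])
  expect_named(plan$color_groups,
               c("A52A2A", "FF0000", "FFC0CB", "NOCOLOR"))
  expect_identical(lengths(plan$color_groups[c("A52A2A", "FF0000", "FFC0CB")]),
                   c(A52A2A = 2L, FF0000 = 3L, FFC0CB = 2L))
})

test_that("a scheme with no edits yields an empty plan and a nothing-selected warning", {
  s <- scheme_of(c("A", "B", "C"))
  expect_warning(plan <- deconstruct(s), class = "tipsort_nothing_selected")
  expect_length(plan$color_groups, 0L)
  expect_length(plan$annot_groups, 0L)
  expect_length(plan$combo_groups, 0L)
})

test_that("the doubly-absent combo pair needs a fully-attributed companion", {
  # colors and annotations used, but never on the same tip: no NONAME_NOCOLOR
  s <- scheme_of(c("A", "B", "C"),
                 color = c("FF0000", NA, NA),
                 annotation = c(NA, "G1", NA))
  plan <- deconstruct(s)
  expect_false("NONAME_NOCOLOR" %in% names(plan$combo_groups))
  # with one fully-attributed tip, the pair appears
  s2 <- scheme_of(c("A", "B", "C", "D"),
                  color = c("FF0000", NA, NA, "FF0000"),
                  annotation = c(NA, "G1", NA, "G1"))
  plan2 <- deconstruct(s2)
  expect_identical(plan2$combo_groups$NONAME_NOCOLOR$labels, "C")
})

test_that("combo_strict limits COMBO to fully-attributed pairs", {
  s <- scheme_of(c("A", "B", "C", "D"),
                 color = c("FF0000", "FF0000", NA, NA),
                 annotation = c("G1", NA, "G1", NA))
  plan <- deconstruct(s, combo_strict = TRUE)
  expect_named(plan$combo_groups, "G1_FF0000")
})

test_that("deconstruction matches the brute-force bucketing oracle with its invariants", {
  set.seed(202)
  for (i in 1:60) {
    s <- random_scheme(n = sample(5:60, 1),
                       p_col = stats::runif(1), p_ann = stats::runif(1))
    strict <- i %% 3 == 0
    plan <- suppressWarnings(deconstruct(s, combo_strict = strict))
    expect_identical(plan_as_list(plan), oracle_plan(s, combo_strict = strict))

    # partition + count conservation per family (combo can legitimately
    # drop labels only under the emission exceptions, which the oracle
    # already encodes; for the plain families it must be exact)
    for (fam in list(plan$color_groups, plan$annot_groups)) {
      if (length(fam) == 0L) next
      all_labels <- unlist(fam, use.names = FALSE)
      expect_identical(sort(all_labels), sort(s$label))
      expect_identical(anyDuplicated(all_labels), 0L)
    }
    # refinement: every combo group inside exactly one color and one annot group
    for (g in plan$combo_groups) {
      cg <- plan$color_groups[[g$color]]
      ag <- plan$annot_groups[[g$annotation]]
      expect_true(all(g$labels %in% cg))
      expect_true(all(g$labels %in% ag))
    }
    # determinism
    expect_identical(plan_as_list(suppressWarnings(
      deconstruct(s, combo_strict = strict))), plan_as_list(plan))
  }
})
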