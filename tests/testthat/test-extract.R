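make_scheme <- function(label, color = NA, annotation = NA) {
  s <- data.frame(label = label,
                  color = rep_len(color, length(label)),
                  annotation = rep_len(annotation, length(label)),
                  stringsAsFactors = FALSE)
  attr(s, "duplicates") <- data.frame(label = character(0), count = integer(0),
                                      stringsAsFactors = FALSE)
  class(s) <- c("tipsort_scheme", "data.frame")
  s
}

make_records <- function(labels, seed = 5) {
  set.seed(seed)
  data.frame(header = labels,
             sequence = vapply(labels, function(x) {
               paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
             }, ""),
             stringsAsFactors = FALSE)
}

test_that("a monochromatic plan writes exactly the colored file and NOCOLOR.fas", {
  s <- make_scheme(LETTERS[1:20],
                   color = ifelse(LETTERS[1:20] %in% c("H", "I"),
                                  NA, "FF0000"))
  rec <- make_records(LETTERS[1:20])
  out <- withr::local_tempdir()
  man <- extract_sequences(deconstruct(s), rec, out)

  expect_setequal(list.files(file.path(out, "COLOR")),
                  c("FF0000.fas", "NOCOLOR.fas"))
  expect_identical(sort(man$written$filename), c("FF0000.fas", "NOCOLOR.fas"))
  noc <- read_fasta(file = file.path(out, "COLOR", "NOCOLOR.fas"))
  expect_identical(noc$header, c("H", "I"))
  # content fidelity, byte for byte
  expect_identical(noc$sequence, rec$sequence[rec$header %in% c("H", "I")])
  red <- read_fasta(file = file.path(out, "COLOR", "FF0000.fas"))
  expect_identical(nrow(red), 18L)
})

test_that("an annotation over two colors lands whole in ANNOT and split in COMBO", {
  n_ref <- 12; n_env <- 8; n_out <- 5
  labels <- c(sprintf("Reference_%02d", 1:n_ref),
              sprintf("Uncultured organism %02d", 1:n_env),
              sprintf("Outgroup_%02d", 1:n_out))
  s <- make_scheme(
    labels,
    color = c(rep("FF0000", n_ref), rep("0000FF", n_env), rep(NA, n_out)),
    annotation = c(rep("Florideophyceae", n_ref + n_env), rep(NA, n_out))
  )
  rec <- make_records(labels)
  out <- withr::local_tempdir()
  extract_sequences(deconstruct(s), rec, out)

  flo <- read_fasta(file = file.path(out, "ANNOT", "Florideophyceae.fas"))
  expect_identical(flo$header, labels[1:(n_ref + n_env)])
  ref <- read_fasta(file = file.path(out, "COMBO", "Florideophyceae_FF0000.fas"))
  env <- read_fasta(file = file.path(out, "COMBO", "Florideophyceae_0000FF.fas"))
  expect_identical(ref$header, labels[1:n_ref])
  expect_identical(env$header, labels[n_ref + (1:n_env)])
  # COMBO files for the annotation jointly reproduce its ANNOT file
  expect_setequal(c(ref$header, env$header), flo$header)
})

test_that("unmatched labels are skipped; fully-unmatched groups produce no file", {
  s <- make_scheme(c("A", "B", "C", "D"),
                   color = c("FF0000", "FF0000", "00FF00", "00FF00"))
  rec <- make_records(c("A", "B"))
  out <- withr::local_tempdir()
  expect_warning(man <- extract_sequences(deconstruct(s), rec, out),
                 class = "tipsort_skipped_label")
  expect_identical(list.files(file.path(out, "COLOR")), "FF0000.fas")
  expect_setequal(man$skipped_labels, c("C", "D"))
  expect_true(all(man$written$sequence_count >= 1L))
})

test_that("duplicate-header labels contribute all their records and counts conserve", {
  s <- make_scheme(c("A", "B", "C"), color = c("FF0000", "FF0000", NA))
  rec <- rbind(make_records(c("A", "B", "C")),
               make_records("A", seed = 99))
  out <- withr::local_tempdir()
  man <- extract_sequences(deconstruct(s), rec, out)
  red <- read_fasta(file = file.path(out, "COLOR", "FF0000.fas"))
  expect_identical(red$header, c("A", "A", "B"))
  # conservation: sequences written across COLOR/ = matched multiplicity
  expect_identical(sum(man$written$sequence_count[man$written$folder == "COLOR"]),
                   4L)
})

test_that("summary files relate each color and annotation to its written labels", {
  s <- make_scheme(LETTERS[1:6],
                   color = c(rep("FF0000", 3), rep(NA, 3)),
                   annotation = c(NA, NA, NA, "G1", "G1", NA))
  rec <- make_records(LETTERS[1:6])
  out <- withr::local_tempdir()
  plan <- deconstruct(s)
  man <- extract_sequences(plan, rec, out)
  write_summary_by_color(plan, man, out)
  write_summary_by_annotation(plan, man, out)

  col <- readLines(file.path(out, "summary_by_color.txt"))
  expect_true(any(grepl("^COLOR FF0000 \\(3", col)))
  expect_true(any(grepl("^COLOR NOCOLOR \\(3", col)))
  sec <- which(grepl("^COLOR FF0000", col))
  expect_identical(col[sec + (1:3)], c("A", "B", "C"))

  ann <- readLines(file.path(out, "summary_by_annotation.txt"))
  expect_true(any(grepl("^ANNOT G1 \\(2", ann)))

  # no colors -> no summary_by_color file
  s2 <- make_scheme(c("A", "B"), annotation = c("G1", NA))
  out2 <- withr::local_tempdir()
  plan2 <- deconstruct(s2)
  man2 <- extract_sequences(plan2, make_records(c("A", "B")), out2)
  write_summary_by_color(plan2, man2, out2)
  expect_false(file.exists(file.path(out2, "summary_by_color.txt")))
})

test_that("annotation names are sanitized for the filesystem and collisions are fatal", {
  expect_identical(sanitize_name("Group1"), "Group1")
  expect_identical(sanitize_name("uncultured organism/16S"),
                   "uncultured_organism_16S")

  s <- make_scheme(c("A", "B"), annotation = c("G 1", "G/1"))
  rec <- make_records(c("A", "B"))
  expect_error(
    extract_sequences(deconstruct(s), rec, withr::local_tempdir()),
    class = "tipsort_io_error"
  )

  s2 <- make_scheme(c("A", "B"), annotation = c("G 1", NA))
  out <- withr::local_tempdir()
  man <- extract_sequences(deconstruct(s2), rec, out)
  expect_true(file.exists(file.path(out, "ANNOT", "G_1.fas")))
  expect_identical(man$renamed,
                   data.frame(raw = "G 1", sanitized = "G_1",
                              stringsAsFactors = FALSE))
})

test_that("existing outputs are protected unless force is given; re-runs are byte-identical", {
  s <- make_scheme(c("A", "B"), color = c("FF0000", NA))
  rec <- make_records(c("A", "B"))
  out <- withr::local_tempdir()
  plan <- deconstruct(s)
  extract_sequences(plan, rec, out)
  f <- file.path(out, "COLOR", "FF0000.fas")
  bytes1 <- readBin(f, "raw", file.info(f)$size)

  expect_error(extract_sequences(plan, rec, out),
               class = "tipsort_io_error")
  extract_sequences(plan, rec, out, force = TRUE)
  bytes2 <- readBin(f, "raw", file.info(f)$size)
  expect_identical(bytes1, bytes2)
})
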