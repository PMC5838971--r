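# Materializing an extraction plan as folders of FASTA files.
#
# Layout under <outdir>:
#   COLOR/<HEX>.fas, COLOR/NOCOLOR.fas
#   ANNOT/<annotation>.fas, ANNOT/NONAME.fas
#   COMBO/<annotation>_<HEX>.fas      (placeholder components allowed)
#   summary_by_color.txt, summary_by_annotation.txt, manifest.txt
#
# Empty groups (no matched sequences) are never written; a label matched to
# duplicated FASTA headers contributes all of its records; sequences are
# written in plan order so re-runs are byte-identical.

#' Make an annotation filesystem-safe
#'
#' Characters outside `[A-Za-z0-9._-]` become `_`. Used for annotation
#' components of output filenames; hex color codes never need it.
#'
#' @param raw Non-empty annotation text.
#' @return The sanitized name.
#' @examples
#' sanitize_name("uncultured organism/16S")
#' @export
sanitize_name <- function(raw) {
  stopifnot(is.character(raw), all(nzchar(raw)))
  gsub("[^A-Za-z0-9._-]", "_", raw)
}

#' Write the extraction plan to disk
#'
#' Creates `COLOR/`, `ANNOT/` and `COMBO/` under `outdir` (only the families
#' the plan contains), writes one sequential FASTA per group named after its
#' hex code, sanitized annotation, or `annotation_color` combination, and
#' returns a manifest of what was written. Labels present in the plan but
#' unmatched in the FASTA are skipped with a warning (extraction proceeds on
#' the matched intersection); groups left empty after matching produce no
#' file. Filename collisions after sanitization, and existing output files
#' without `force = TRUE`, are fatal.
#'
#' @param plan A [`tipsort_plan`][deconstruct].
#' @param records FASTA records from [read_fasta()].
#' @param outdir Output directory (created if needed).
#' @param force Overwrite existing output files.
#' @inheritParams check_concordance
#' @return A `tipsort_manifest`: `written` data frame
#'   (`folder`, `filename`, `sequence_count`), `skipped_labels`, `renamed`
#'   data frame of sanitization changes, and `group_labels` (per family, the
#'   matched labels actually written for each group, used by the summary
#'   writers).
#' @export
extract_sequences <- function(plan, records, outdir, force = FALSE,
                              match_mode = c("full", "first"),
                              translate_underscores = FALSE) {
  stopifnot(inherits(plan, "tipsort_plan"), is.data.frame(records))
  match_mode <- match.arg(match_mode)

  manifest <- structure(
    list(
      written = data.frame(folder = character(0), filename = character(0),
                           sequence_count = integer(0),
                           stringsAsFactors = FALSE),
      skipped_labels = character(0),
      renamed = data.frame(raw = character(0), sanitized = character(0),
                           stringsAsFactors = FALSE),
      group_labels = list(COLOR = list(), ANNOT = list(), COMBO = list())
    ),
    class = "tipsort_manifest"
  )

  # group table: folder, filename, key, labels
  groups <- list()
  add <- function(folder, filename, key, labels) {
    groups[[length(groups) + 1L]] <<-
      list(folder = folder, filename = filename, key = key, labels = labels)
  }
  fname_ann <- function(a) if (a == "NONAME") a else sanitize_name(a)
  for (h in names(plan$color_groups)) {
    add("COLOR", paste0(h, ".fas"), h, plan$color_groups[[h]])
  }
  for (a in names(plan$annot_groups)) {
    add("ANNOT", paste0(fname_ann(a), ".fas"), a, plan$annot_groups[[a]])
  }
  for (k in names(plan$combo_groups)) {
    g <- plan$combo_groups[[k]]
    add("COMBO", paste0(fname_ann(g$annotation), "_", g$color, ".fas"),
        k, g$labels)
  }
  if (length(groups) == 0L) {
    return(manifest)
  }

  # record sanitization changes
  anns <- unique(c(names(plan$annot_groups),
                   vapply(plan$combo_groups, `[[`, "", "annotation")))
  anns <- setdiff(anns, "NONAME")
  changed <- anns[sanitize_name(anns) != anns]
  manifest$renamed <- data.frame(raw = changed,
                                 sanitized = sanitize_name(changed),
                                 stringsAsFactors = FALSE)

  # collision check, case-insensitive per folder
  folder <- vapply(groups, `[[`, "", "folder")
  filename <- vapply(groups, `[[`, "", "filename")
  lower <- paste(folder, tolower(filename), sep = "/")
  if (anyDuplicated(lower)) {
    d <- lower[duplicated(lower)][1L]
    offenders <- vapply(groups[lower == d], `[[`, "", "key")
    io_error(sprintf(
      "output filename collision after sanitization: groups '%s' and '%s' both map to %s",
      offenders[1L], offenders[2L], filename[which(lower == d)[1L]]
    ))
  }

  paths <- file.path(outdir, folder, filename)
  if (!force) {
    clash <- paths[file.exists(paths)]
    if (length(clash) > 0L) {
      io_error(sprintf(
        "output file(s) already exist (use force = TRUE to overwrite): %s",
        paste(clash, collapse = ", ")
      ))
    }
  }
  for (d in file.path(outdir, unique(folder))) {
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE)) {
      io_error(sprintf("cannot create output directory '%s'", d))
    }
  }

  # label -> record indices under the matching mode
  fkey <- match_key(records$header, match_mode, translate_underscores)
  idx_of <- split(seq_len(nrow(records)), fkey)

  skipped <- character(0)
  for (g in seq_along(groups)) {
    labels <- groups[[g]]$labels
    keys <- match_key(labels, "full", translate_underscores)
    hit <- keys %in% names(idx_of)
    skipped <- c(skipped, labels[!hit])
    if (!any(hit)) next
    idx <- unlist(idx_of[keys[hit]], use.names = FALSE)
    write_fasta(records[idx, , drop = FALSE], paths[g])
    manifest$written <- rbind(manifest$written, data.frame(
      folder = folder[g], filename = filename[g],
      sequence_count = length(idx), stringsAsFactors = FALSE
    ))
    manifest$group_labels[[folder[g]]][[groups[[g]]$key]] <- labels[hit]
  }
  manifest$skipped_labels <- unique(skipped)
  if (length(manifest$skipped_labels) > 0L) {
    tipsort_warn(
      sprintf("%d planned label(s) had no matching FASTA record and were skipped: %s",
              length(manifest$skipped_labels),
              paste(manifest$skipped_labels, collapse = ", ")),
      "tipsort_skipped_label"
    )
  }

  write_manifest(manifest, outdir)
  manifest
}

write_manifest <- function(manifest, outdir) {
  lines <- c("tipsort output manifest", "")
  if (nrow(manifest$written) > 0L) {
    lines <- c(lines, sprintf("%s/%s\t%d sequence(s)",
                              manifest$written$folder,
                              manifest$written$filename,
                              manifest$written$sequence_count))
  } else {
    lines <- c(lines, "no files written")
  }
  if (length(manifest$skipped_labels) > 0L) {
    lines <- c(lines, "", "skipped labels (no FASTA match):",
               paste0("  ", manifest$skipped_labels))
  }
  if (nrow(manifest$renamed) > 0L) {
    lines <- c(lines, "", "annotation names sanitized for the filesystem:",
               sprintf("  %s -> %s", manifest$renamed$raw,
                       manifest$renamed$sanitized))
  }
  writeLines(lines, file.path(outdir, "manifest.txt"))
  invisible(NULL)
}

#' @export
print.tipsort_manifest <- function(x, ...) {
  cat(sprintf("Extraction manifest: %d file(s) written, %d label(s) skipped\n",
              nrow(x$written), length(x$skipped_labels)))
  if (nrow(x$written) > 0L) {
    cat(sprintf("  %s/%s (%d)\n", x$written$folder, x$written$filename,
                x$written$sequence_count), sep = "")
  }
  invisible(x)
}

#' Write the summary_by_color file
#'
#' Because output FASTA files in `COLOR/` are named by hex code rather than
#' by a human color name, `summary_by_color.txt` relates each hex code (and
#' `NOCOLOR`) to the sequence labels written under it, one section per
#' color.
#'
#' @param plan A [`tipsort_plan`][deconstruct].
#' @param manifest Manifest returned by [extract_sequences()] for this plan.
#' @param outdir Output directory.
#' @return Invisibly, the file path, or `NULL` when the plan has no color
#'   groups (no file is written).
#' @export
write_summary_by_color <- function(plan, manifest, outdir) {
  write_summary_family(plan$color_groups, manifest$group_labels$COLOR,
                       "COLOR", file.path(outdir, "summary_by_color.txt"))
}

#' Write the summary_by_annotation file
#'
#' Companion of [write_summary_by_color()] for the `ANNOT/` family.
#'
#' @inheritParams write_summary_by_color
#' @return Invisibly, the file path, or `NULL` when the plan has no
#'   annotation groups.
#' @export
write_summary_by_annotation <- function(plan, manifest, outdir) {
  write_summary_family(plan$annot_groups, manifest$group_labels$ANNOT,
                       "ANNOT", file.path(outdir, "summary_by_annotation.txt"))
}

write_summary_family <- function(groups, written_labels, family, path) {
  if (length(groups) == 0L) return(invisible(NULL))
  lines <- character(0)
  for (key in names(groups)) {
    labels <- written_labels[[key]]
    if (is.null(labels)) next  # group fully unmatched: no file, no section
    lines <- c(lines,
               sprintf("%s %s (%d sequence label(s))", family, key,
                       length(labels)),
               labels, "")
  }
  writeLines(lines, path)
  invisible(path)
}
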