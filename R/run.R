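# End-to-end pipeline: parse -> concordance -> deconstruct -> extract.
# tipsort() is the programmatic surface (errors propagate as classed
# conditions); tipsort_run() maps those conditions to shell exit statuses
# for the command-line wrapper and adds nothing else.

#' Partition a FASTA file by the color/annotation edits of a FigTree tree
#'
#' Runs the full pipeline: parse the taxa block of the FigTree-saved NEXUS
#' file, cross-check tip labels against the FASTA headers (warnings for
#' duplicates and missing labels; fatal only when nothing matches),
#' deconstruct the selection scheme, and write the `COLOR/`, `ANNOT/` and
#' `COMBO/` FASTA subsets plus `summary_by_color.txt`,
#' `summary_by_annotation.txt`, `manifest.txt` and `concordance_report.txt`
#' under `outdir`.
#'
#' @param nexus Path to the FigTree-saved NEXUS file.
#' @param fasta Path to the FASTA file the tree was built from.
#' @param outdir Output directory (created if needed).
#' @inheritParams parse_figtree_nexus
#' @inheritParams check_concordance
#' @inheritParams deconstruct
#' @param force Overwrite existing output files.
#' @return Invisibly, a `tipsort_result` list with elements `scheme`,
#'   `plan`, `report` (concordance) and `manifest`.
#' @examples
#' fx <- generate_fixture(fixture_spec(
#'   n_taxa = 20,
#'   color_assign = ifelse(LETTERS[1:20] %in% c("H", "I"), NA, "FF0000"),
#'   seed = 42
#' ), dir = tempfile("fx"))
#' out <- tempfile("run")
#' res <- tipsort(fx$paths[["nexus"]], fx$paths[["fasta"]], out)
#' res$manifest
#' @export
tipsort <- function(nexus, fasta, outdir,
                    annotation_key = "!name",
                    match_mode = c("full", "first"),
                    translate_underscores = FALSE,
                    combo_strict = FALSE,
                    force = FALSE) {
  match_mode <- match.arg(match_mode)
  taxa <- parse_figtree_nexus(file = nexus, annotation_key = annotation_key)
  records <- read_fasta(file = fasta)
  scheme <- build_scheme(taxa)
  report <- check_concordance(scheme, records, match_mode = match_mode,
                              translate_underscores = translate_underscores)
  plan <- deconstruct(scheme, combo_strict = combo_strict)
  manifest <- extract_sequences(plan, records, outdir, force = force,
                                match_mode = match_mode,
                                translate_underscores = translate_underscores)
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    io_error(sprintf("cannot create output directory '%s'", outdir))
  }
  write_summary_by_color(plan, manifest, outdir)
  write_summary_by_annotation(plan, manifest, outdir)
  writeLines(format(report), file.path(outdir, "concordance_report.txt"))
  invisible(structure(
    list(scheme = scheme, plan = plan, report = report, manifest = manifest),
    class = "tipsort_result"
  ))
}

#' @export
print.tipsort_result <- function(x, ...) {
  print(x$scheme)
  print(x$plan)
  print(x$manifest)
  invisible(x)
}

#' Run the pipeline with shell-style exit statuses
#'
#' Same arguments and behavior as [tipsort()], but fatal conditions are
#' caught, their message emitted, and a status code returned instead of an
#' R error: `0` success (including warn-and-continue runs), `2` parse
#' error, `3` zero labels matched, `4` I/O or filename-collision error.
#' This is the function the command-line script (`inst/scripts/tipsort.R`)
#' calls; it composes the module operations and adds no behavior of its
#' own.
#'
#' @inheritParams tipsort
#' @param quiet Suppress the printed run summary.
#' @return Invisibly, the integer status; on success the `tipsort_result`
#'   is attached as attribute `"result"`.
#' @export
tipsort_run <- function(nexus, fasta, outdir,
                        annotation_key = "!name",
                        match_mode = c("full", "first"),
                        translate_underscores = FALSE,
                        combo_strict = FALSE,
                        force = FALSE,
                        quiet = FALSE) {
  status <- 0L
  result <- NULL
  tryCatch(
    {
      result <- tipsort(nexus, fasta, outdir,
                        annotation_key = annotation_key,
                        match_mode = match_mode,
                        translate_underscores = translate_underscores,
                        combo_strict = combo_strict,
                        force = force)
    },
    tipsort_parse_error = function(e) {
      message("parse error: ", conditionMessage(e))
      status <<- 2L
    },
    tipsort_zero_match_error = function(e) {
      message("concordance error: ", conditionMessage(e))
      status <<- 3L
    },
    tipsort_io_error = function(e) {
      message("I/O error: ", conditionMessage(e))
      status <<- 4L
    }
  )
  if (status == 0L && !quiet && !is.null(result)) {
    print(result)
  }
  out <- status
  if (!is.null(result)) attr(out, "result") <- result
  invisible(out)
}
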