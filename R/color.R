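#' Normalize a FigTree color value to a 6-digit uppercase hex code
#'
#' FigTree serializes tip colors in its NEXUS output in one of two ways,
#' depending on version: as `#rrggbb` hex text, or as a signed decimal
#' integer holding the two's-complement 32-bit ARGB value (e.g. pure red,
#' alpha FF, is `-65536` = `0xFFFF0000`). Both encodings map to the same
#' 24-bit RGB color; this function reduces either to the uppercase 6-hex-digit
#' RGB code used to name color output files, so that `#FF0000` and `-65536`
#' select the same group.
#'
#' @param raw A single color value as written in the file: either `#` followed
#'   by six hex digits, or a (possibly signed) decimal integer.
#' @return A 6-character uppercase hex string, or `NA_character_` (with an
#'   `unrecognized-color` warning) when `raw` matches neither encoding.
#' @examples
#' normalize_color("#ff0000")  # "FF0000"
#' normalize_color("-65536")   # "FF0000" (ARGB 0xFFFF0000, low 24 bits kept)
#' normalize_color("#00ff00")  # "00FF00"
#' @export
normalize_color <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  raw <- trimws(raw)
  if (grepl("^#[0-9a-fA-F]{6}$", raw)) {
    return(toupper(substring(raw, 2L)))
  }
  if (grepl("^[+-]?[0-9]+$", raw)) {
    v <- suppressWarnings(as.numeric(raw))
    # two's-complement 32-bit reinterpretation, then drop the alpha byte
    if (is.finite(v) && abs(v) < 2^53) {
      rgb <- (v %% 2^32) %% 2^24
      return(sprintf("%06X", as.integer(rgb)))
    }
  }
  tipsort_warn(
    sprintf("unrecognized color value '%s'; treating color as absent", raw),
    "tipsort_unrecognized_color"
  )
  NA_character_
}
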