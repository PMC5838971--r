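# Internal helpers: classed conditions, text slurping, EOL normalization,
# local seed scoping.

# Fatal errors carry a class so callers (tipsort_run, the CLI) can map them
# to distinct exit statuses without string-matching messages.
tipsort_error <- function(message, class, data = NULL, call. = sys.call(-1)) {
  cond <- structure(
    class = c(class, "tipsort_error", "error", "condition"),
    list(message = message, call = call., data = data)
  )
  stop(cond)
}

parse_error <- function(message, ...) {
  tipsort_error(message, "tipsort_parse_error", ...)
}

zero_match_error <- function(message, ...) {
  tipsort_error(message, "tipsort_zero_match_error", ...)
}

io_error <- function(message, ...) {
  tipsort_error(message, "tipsort_io_error", ...)
}

# All advisory conditions ("warn and continue") funnel through here.
tipsort_warn <- function(message, class = character(0)) {
  warning(warningCondition(message, class = c(class, "tipsort_warning")))
  invisible(NULL)
}

# Read a whole file as a single string, byte-preserving (no EOL translation),
# or pass `text` through. Exactly one of the two must be given.
slurp <- function(file = NULL, text = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `file` or `text`")
  }
  if (!is.null(text)) {
    return(paste(text, collapse = "\n"))
  }
  if (!file.exists(file)) {
    io_error(sprintf("input file not found: '%s'", file))
  }
  n <- file.info(file)$size
  readChar(file, nchars = n, useBytes = TRUE)
}

# CRLF and lone CR become LF, so downstream code sees one convention
# regardless of the platform that wrote the file.
normalize_eol <- function(x) {
  gsub("\r\n?", "\n", x)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Header/label comparison key under the configured matching mode.
match_key <- function(x, match_mode = "full", translate_underscores = FALSE) {
  if (match_mode == "first") {
    x <- sub("[ \t].*$", "", x)
  }
  if (translate_underscores) {
    x <- chartr("_", " ", x)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
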