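#' Collapse runs of whitespace
#'
#' Transcripts arrive from heterogeneous exports (plain text, spreadsheet
#' cells, HTML-derived dumps), so all text is normalized on read: runs of
#' whitespace (including newlines and tabs) collapse to a single space and
#' leading/trailing whitespace is removed. Every downstream word and
#' sentence operation assumes this normal form.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_whitespace <- function(x) {
  trimws(gsub("[[:space:]]+", " ", x))
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic package operations go
# through this so that a seed argument fully determines the result without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (so 0.5 -> 1, 1.5 -> 2), used for prorating
# detail counts across sentence boundaries; base round() rounds half to
# even, which is not the stated half-up convention.
round_half_up <- function(x) {
  floor(x + 0.5)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
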