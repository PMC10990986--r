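#' Remove researcher prompts from narrative text
#'
#' Interviewer prompting (e.g., "tell me more about that") is not part of the
#' participant's narrative and, if left in, would be scored like any other
#' content. Prompts are supplied by the user as literal strings (or regular
#' expressions with `fixed = FALSE`); there is no built-in prompt lexicon.
#' Every occurrence of every prompt is removed and the surrounding whitespace
#' collapsed. Zero matches is not an error.
#'
#' @param text character vector of narrative text.
#' @param prompts character vector of prompts to remove; empty means no-op.
#' @param fixed if `TRUE` (default) prompts are matched as literal strings,
#'   otherwise as regular expressions.
#' @return character vector with prompts removed and whitespace normalized.
#' @examples
#' strip_prompts("tell me more about that. We left at dawn.",
#'               "tell me more about that.")
#' @export
strip_prompts <- function(text, prompts = character(), fixed = TRUE) {
  stopifnot(is.character(text))
  prompts <- as.character(prompts)
  prompts <- prompts[nzchar(prompts)]
  if (length(prompts) == 0L) {
    return(text)
  }
  out <- text
  for (p in prompts) {
    out <- gsub(p, " ", out, fixed = fixed)
  }
  normalize_whitespace(out)
}

#' Default abbreviation list for sentence splitting
#'
#' Tokens (case-insensitive, stored without the trailing period) after which
#' a period does not end a sentence. Covers common English titles, Latin
#' abbreviations, and month/street shorthand typical of interview
#' transcripts.
#'
#' @return character vector of abbreviations, lower case, no trailing period.
#' @export
ai_abbreviations <- function() {
  c(
    "dr", "mr", "mrs", "ms", "prof", "rev", "hon", "st", "jr", "sr",
    "vs", "etc", "e.g", "i.e", "cf", "al", "approx", "dept", "est",
    "fig", "no", "vol", "jan", "feb", "mar", "apr", "jun", "jul", "aug",
    "sep", "sept", "oct", "nov", "dec", "mon", "tue", "wed", "thu", "fri",
    "sat", "sun", "ave", "blvd", "rd", "mt", "ft"
  )
}

# A token ends a sentence when it terminates in ., !, ?, or an ellipsis,
# unless the token is an abbreviation or (for a period) a single initial
# like "J.".
.is_terminal <- function(token, abbreviations) {
  # strip trailing closing quotes/brackets so «word."» still terminates
  core <- sub("[\"'”’)\\]]+$", "", token)
  if (grepl("[!?]$", core) || grepl("(…|\\.\\.\\.)$", core)) {
    return(TRUE)
  }
  if (!grepl("\\.$", core)) {
    return(FALSE)
  }
  bare <- tolower(sub("\\.$", "", core))
  if (bare %in% abbreviations) {
    return(FALSE)
  }
  # single-letter initials ("J. Smith") do not split
  if (grepl("^[A-Za-z]$", bare)) {
    return(FALSE)
  }
  TRUE
}

#' Split text into sentences
#'
#' Rule-based sentence boundary detection: text is scanned token by token and
#' a boundary is placed after any token carrying terminal punctuation
#' (`.`, `!`, `?`, ellipsis), unless the token is a known abbreviation or a
#' single initial. Text without terminal punctuation yields a single
#' sentence — this is the characteristic failure mode for transcripts typed
#' without punctuation, and it is deliberate: the splitter never invents
#' boundaries.
#'
#' The backend is pluggable in principle (any function mapping text to an
#' ordered, exhaustive sentence list can stand behind the pipeline); this
#' rule-based splitter is the default and the one the test suite pins.
#'
#' @param text a single character string (whitespace-normalized).
#' @param abbreviations character vector of abbreviations (lower case, no
#'   trailing dot) that block a period from ending a sentence.
#' @return a tibble with columns `index` (0-based), `text`, `word_count`;
#'   zero rows for empty input.
#' @examples
#' split_sentences("I went home. It was raining.")
#' split_sentences("We met Dr. Smith at noon.")
#' @export
split_sentences <- function(text, abbreviations = ai_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- normalize_whitespace(text)
  if (!nzchar(text)) {
    return(tibble::tibble(
      index = integer(), text = character(), word_count = integer()
    ))
  }
  tokens <- strsplit(text, " ", fixed = TRUE)[[1]]
  ends <- vapply(tokens, .is_terminal, logical(1),
                 abbreviations = abbreviations, USE.NAMES = FALSE)
  ends[length(tokens)] <- TRUE  # final fragment is always a sentence
  stops <- which(ends)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  sents <- mapply(
    function(a, b) paste(tokens[a:b], collapse = " "),
    starts, stops
  )
  tibble::tibble(
    index = seq_along(sents) - 1L,
    text = as.character(sents),
    word_count = as.integer(stops - starts + 1L)
  )
}

#' Count words in text
#'
#' A word is a whitespace-delimited token; punctuation stays attached to its
#' token and hyphens/em-dashes do not split tokens. This is the word unit
#' used everywhere in the package, including the internal/external word
#' counts that proxy manual detail counts.
#'
#' @param text character vector.
#' @return integer vector of token counts; empty or whitespace-only text
#'   counts 0.
#' @examples
#' word_count("he had a brown hat")  # 5
#' @export
word_count <- function(text) {
  stopifnot(is.character(text))
  text <- normalize_whitespace(text)
  n <- lengths(strsplit(text, " ", fixed = TRUE))
  n[!nzchar(text)] <- 0L
  as.integer(n)
}

#' Sentence table for a narrative corpus
#'
#' Applies [split_sentences()] to each narrative and stacks the results.
#'
#' @param narratives a narrative tibble (see [read_narratives()]).
#' @param abbreviations passed to [split_sentences()].
#' @return tibble with columns `narrative_id`, `index`, `text`, `word_count`.
#' @export
sentence_table <- function(narratives, abbreviations = ai_abbreviations()) {
  stopifnot(is.data.frame(narratives), "narrative_id" %in% names(narratives))
  parts <- lapply(seq_len(nrow(narratives)), function(i) {
    s <- split_sentences(narratives$text[i], abbreviations)
    if (nrow(s) == 0L) return(NULL)
    s$narrative_id <- narratives$narrative_id[i]
    s
  })
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      narrative_id = character(), index = integer(),
      text = character(), word_count = integer()
    ))
  }
  out[, c("narrative_id", "index", "text", "word_count")]
}

#' Remove sentences with more than `max_details` details
#'
#' Sentences carrying more than eight manual details are overwhelmingly
#' transcription artefacts: stretches typed with little or no punctuation
#' that the splitter cannot divide, so one "sentence" holds much of the
#' narrative. They are removed from annotated (training/validation) corpora,
#' and each narrative's validation detail counts are decremented by the
#' details removed with its dropped sentences. The strict rule is
#' "more than" `max_details`: a sentence with exactly eight details is kept.
#'
#' This filter applies only to annotated corpora during training and
#' validation; the scoring pipeline for new narratives never calls it.
#'
#' @param sentences a sentence-annotation tibble as returned by
#'   [sentence_annotations()] (must carry `detail_count`, `detail_internal`,
#'   `detail_external`, `internal_words`).
#' @param max_details integer threshold, default 8.
#' @return a list with elements `retained` (tibble), `removed` (tibble), and
#'   `adjustments`: one row per narrative with any removal, giving the
#'   internal/external details and words removed.
#' @export
filter_long_sentences <- function(sentences, max_details = 8L) {
  if (!is.numeric(max_details) || length(max_details) != 1L ||
      is.na(max_details) || max_details < 1) {
    stopf("`max_details` must be a single integer >= 1, got %s",
          deparse(max_details))
  }
  need <- c("narrative_id", "index", "word_count", "detail_count",
            "detail_internal", "detail_external", "internal_words")
  missing <- setdiff(need, names(sentences))
  if (length(missing) > 0L) {
    stopf("`sentences` lacks column(s): %s", paste(missing, collapse = ", "))
  }
  drop <- sentences$detail_count > max_details
  removed <- sentences[drop, , drop = FALSE]
  retained <- sentences[!drop, , drop = FALSE]
  if (nrow(removed) == 0L) {
    adjustments <- tibble::tibble(
      narrative_id = character(),
      internal_details_removed = numeric(),
      external_details_removed = numeric(),
      internal_words_removed = numeric(),
      external_words_removed = numeric()
    )
  } else {
    adjustments <- removed |>
      dplyr::group_by(.data$narrative_id) |>
      dplyr::summarise(
        internal_details_removed = sum(.data$detail_internal),
        external_details_removed = sum(.data$detail_external),
        internal_words_removed = sum(.data$internal_words),
        external_words_removed = sum(.data$word_count - .data$internal_words),
        .groups = "drop"
      )
  }
  list(retained = retained, removed = removed, adjustments = adjustments)
}
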