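#' Convert a class prediction into internal/external word counts
#'
#' A sentence classified as class `c` contributes
#' `fraction(c) * word_count` internal words and the remainder external
#' words. This is the word-level analogue of counting internal and external
#' details, and it conserves words exactly: internal + external equals the
#' sentence's word count.
#'
#' @param word_count integer vector of sentence word counts (all positive).
#' @param cls class labels (character or factor), recycled against
#'   `word_count`.
#' @return tibble with columns `internal_words`, `external_words`.
#' @examples
#' score_sentence(10, "P75")  # 7.5 internal, 2.5 external
#' @export
score_sentence <- function(word_count, cls) {
  if (any(word_count <= 0)) stopf("word_count must be positive")
  f <- class_fraction(cls)
  tibble::tibble(
    internal_words = f * word_count,
    external_words = (1 - f) * word_count
  )
}

# Score a table of sentences with a model and aggregate per narrative.
# `mode = "class"` uses the argmax class's representative fraction (the
# default: classify, then sum); `mode = "expected"` uses the
# probability-weighted fraction.
.score_sentence_table <- function(sentences, model,
                                  mode = c("class", "expected")) {
  mode <- match.arg(mode)
  pred <- predict_class(model, sentences)
  if (mode == "class") {
    sc <- score_sentence(sentences$word_count, pred$cls)
  } else {
    pc <- proportion_classes()
    pmat <- as.matrix(pred[, paste0("p_", pc$label)])
    ef <- as.numeric(pmat %*% pc$fraction)
    sc <- tibble::tibble(
      internal_words = ef * sentences$word_count,
      external_words = (1 - ef) * sentences$word_count
    )
  }
  tibble::tibble(
    narrative_id = sentences$narrative_id,
    internal_words = sc$internal_words,
    external_words = sc$external_words,
    word_count = sentences$word_count
  ) |>
    dplyr::group_by(.data$narrative_id) |>
    dplyr::summarise(
      predicted_internal_words = sum(.data$internal_words),
      predicted_external_words = sum(.data$external_words),
      total_words = sum(.data$word_count),
      .groups = "drop"
    )
}

#' Score one narrative
#'
#' Splits the narrative into sentences, predicts each sentence's proportion
#' class, converts predictions to internal/external word counts and sums
#' them. A narrative that is empty after preprocessing scores (0, 0, 0)
#' with `empty = TRUE` and a warning.
#'
#' @param narrative one-row narrative tibble (see [read_narratives()]).
#' @param model an `ai_classifier`.
#' @param prompts optional prompts to strip before scoring (see
#'   [strip_prompts()]).
#' @param mode `"class"` (default) scores with the argmax class's
#'   representative fraction; `"expected"` with the probability-weighted
#'   fraction.
#' @return one-row tibble: `narrative_id`, `predicted_internal_words`,
#'   `predicted_external_words`, `total_words`, `empty`.
#' @export
score_narrative <- function(narrative, model, prompts = character(),
                            mode = c("class", "expected")) {
  stopifnot(is.data.frame(narrative), nrow(narrative) == 1L)
  score_corpus(narrative, model, prompts = prompts, mode = mode)
}

#' Score a corpus of narratives
#'
#' The batch scoring entry point: strip user-supplied prompts, split each
#' narrative into sentences, classify, and sum word counts. No content
#' other than the given prompts is removed — in particular, the
#' long-sentence training filter is never applied here.
#'
#' @param narratives narrative tibble (see [read_narratives()]).
#' @param model an `ai_classifier`.
#' @param prompts optional prompts to strip before scoring.
#' @param mode see [score_narrative()].
#' @param abbreviations passed to the sentence splitter.
#' @return tibble with one row per input narrative, in input order:
#'   `narrative_id`, `predicted_internal_words`,
#'   `predicted_external_words`, `total_words`, `empty`.
#' @export
score_corpus <- function(narratives, model, prompts = character(),
                         mode = c("class", "expected"),
                         abbreviations = ai_abbreviations()) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(narratives), inherits(model, "ai_classifier"))
  nar <- narratives
  nar$text <- strip_prompts(nar$text, prompts)
  sents <- sentence_table(nar, abbreviations)
  scored <- if (nrow(sents) > 0L) {
    .score_sentence_table(sents, model, mode)
  } else {
    tibble::tibble(narrative_id = character(),
                   predicted_internal_words = numeric(),
                   predicted_external_words = numeric(),
                   total_words = numeric())
  }
  out <- dplyr::left_join(
    nar[, "narrative_id", drop = FALSE], scored, by = "narrative_id"
  )
  out$empty <- is.na(out$total_words)
  if (any(out$empty)) {
    warnf("%d narrative(s) empty after preprocessing; scored as (0, 0, 0)",
          sum(out$empty))
    for (col in c("predicted_internal_words", "predicted_external_words",
                  "total_words")) {
      out[[col]][out$empty] <- 0
    }
  }
  out$total_words <- as.integer(round(out$total_words))
  tibble::as_tibble(out)
}
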