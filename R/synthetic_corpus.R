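# Disjoint template vocabularies. Internal sentences draw on a past-tense,
# specific, perceptual lexicon (what episodic detail looks like); external
# sentences draw on a habitual/semantic one (facts, generalities,
# metacognition). Disjointness makes class separability controllable by
# construction; textual realism is a non-goal of the generator.
.internal_lexicon <- c(
  "yesterday", "suddenly", "grabbed", "walked", "smelled", "bright",
  "cold", "sand", "waves", "laughed", "whispered", "corner", "window",
  "red", "jacket", "noticed", "heard", "tasted", "salty", "afternoon",
  "stumbled", "doorway", "flickering", "candle", "shouted", "raindrops",
  "shivered", "platform", "suitcase", "glanced", "crowded", "staircase",
  "humming", "engine", "warm", "blanket", "spilled", "coffee", "sunset",
  "gravel", "footsteps", "creaking", "lantern", "rustling", "meadow",
  "startled", "echoed", "dusty"
)

.external_lexicon <- c(
  "usually", "always", "generally", "believe", "people", "important",
  "typical", "history", "often", "famous", "everyone", "normally",
  "tends", "common", "fact", "known", "society", "opinion", "theory",
  "average", "tradition", "concept", "habit", "routine", "principle",
  "mostly", "rarely", "standard", "culture", "knowledge", "wisdom",
  "custom", "universal", "reputation", "assume", "suppose", "perhaps",
  "category", "definition", "summary", "context", "frequently",
  "apparently", "essentially", "obviously", "statistics", "research",
  "textbook"
)

#' Configuration for the synthetic annotated-corpus generator
#'
#' The generator emulates a multi-study pool of scored interview
#' narratives: several datasets with different internal/external mixes,
#' per-segment manual detail counts tied to word counts (the word-count
#' proxy is built into the generative model), and an optional
#' punctuation-degradation knob reproducing the unpunctuated-transcript
#' failure mode.
#'
#' @param n_narratives total narratives, split as evenly as possible across
#'   `datasets` (default 300, i.e. 100 per default dataset).
#' @param datasets list of per-dataset specs: each a list with `id`,
#'   `weights` (mixing weights over classes P0/P50/P75/P100, summing to 1)
#'   and `tasks` (tags cycled over the dataset's narratives).
#' @param sentences_per_narrative integer range `c(min, max)`.
#' @param words_per_segment integer range for the base segment width `w`;
#'   sentence composition is 2w words for pure sentences, w+w for 50%
#'   internal, 3w+w for 75% internal, so true fractions are exact.
#' @param details_per_word_rate expected manual details per word
#'   (default 0.4, i.e. two details per five words).
#' @param proxy_noise_sd standard deviation of Gaussian noise on per-segment
#'   detail counts (default 1.3, calibrated so narrative-level
#'   corr(details, words) falls in the 0.86-0.98 band typical of manual
#'   scoring).
#' @param punctuation_dropout probability that a sentence terminator is
#'   deleted (default 0).
#' @param seed integer seed; the corpus is a pure function of the config.
#' @return a list of class `ai_generator_config`.
#' @export
generator_config <- function(n_narratives = 300L,
                             datasets = NULL,
                             sentences_per_narrative = c(4L, 10L),
                             words_per_segment = c(3L, 8L),
                             details_per_word_rate = 0.4,
                             proxy_noise_sd = 1.3,
                             punctuation_dropout = 0,
                             seed = 1L) {
  if (is.null(datasets)) {
    datasets <- list(
      list(id = "memories",
           weights = c(P0 = 0.20, P50 = 0.20, P75 = 0.20, P100 = 0.40),
           tasks = "memory"),
      list(id = "simulation",
           weights = c(P0 = 0.25, P50 = 0.25, P75 = 0.25, P100 = 0.25),
           tasks = c("young", "old")),
      list(id = "writing",
           weights = c(P0 = 0.30, P50 = 0.25, P75 = 0.15, P100 = 0.30),
           tasks = "writing")
    )
  }
  if (!is.numeric(n_narratives) || n_narratives < 1) {
    stopf("n_narratives must be a positive integer")
  }
  for (d in datasets) {
    if (is.null(d$id) || is.null(d$weights)) {
      stopf("each dataset spec needs `id` and `weights`")
    }
    if (length(d$weights) != 4L || abs(sum(d$weights) - 1) > 1e-8 ||
        any(d$weights < 0)) {
      stopf("dataset '%s': weights must be 4 non-negative values summing to 1",
            d$id)
    }
  }
  for (rng in list(sentences_per_narrative, words_per_segment)) {
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 1) {
      stopf("ranges must be c(min, max) with 1 <= min <= max")
    }
  }
  if (details_per_word_rate <= 0) stopf("details_per_word_rate must be > 0")
  if (proxy_noise_sd < 0) stopf("proxy_noise_sd must be >= 0")
  if (punctuation_dropout < 0 || punctuation_dropout > 1) {
    stopf("punctuation_dropout must lie in [0, 1]")
  }
  structure(
    list(
      n_narratives = as.integer(n_narratives),
      datasets = datasets,
      sentences_per_narrative = as.integer(sentences_per_narrative),
      words_per_segment = as.integer(words_per_segment),
      details_per_word_rate = details_per_word_rate,
      proxy_noise_sd = proxy_noise_sd,
      punctuation_dropout = punctuation_dropout,
      seed = as.integer(seed)
    ),
    class = "ai_generator_config"
  )
}

.sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
}

.fragment <- function(category, n_words) {
  lex <- if (category == "internal") .internal_lexicon else .external_lexicon
  paste(sample(lex, n_words, replace = TRUE), collapse = " ")
}

# sentence parts for a class: (category, width) pairs whose word counts
# realize the class's internal fraction exactly
.sentence_parts <- function(cls, w) {
  switch(cls,
    P0   = list(c("external", 2L * w)),
    P50  = {
      parts <- list(c("internal", w), c("external", w))
      if (stats::runif(1) < 0.5) rev(parts) else parts
    },
    P75  = {
      parts <- list(c("internal", 3L * w), c("external", w))
      if (stats::runif(1) < 0.5) rev(parts) else parts
    },
    P100 = list(c("internal", 2L * w))
  )
}

#' Generate a synthetic annotated corpus
#'
#' Each narrative is a sequence of sentences whose true internal fraction is
#' exactly one of {0, 0.5, 0.75, 1}, drawn from its dataset's mixing
#' weights. Sentences are composed from two disjoint template vocabularies
#' (perceptual/past-tense for internal content, semantic/habitual for
#' external), with span annotations emitted per contiguous part and manual
#' detail counts generated as
#' `max(0, round(rate * words + Normal(0, proxy_noise_sd)))` — the
#' word-count proxy for detail counts is the generative assumption.
#' Punctuation dropout is applied as a final pass over an otherwise
#' identical corpus, so two configs differing only in
#' `punctuation_dropout` yield the same narratives up to deleted
#' terminators.
#'
#' @param config an [generator_config()] object.
#' @return an `ai_annotations` object; the per-sentence true classes are
#'   recoverable via [sentence_annotations()] when `punctuation_dropout` is
#'   zero.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "ai_generator_config"))
  k <- length(config$datasets)
  per <- diff(round(config$n_narratives * (0:k) / k))
  corpus <- with_seed(config$seed, {
    nar_rows <- list()
    seg_rows <- list()
    for (di in seq_len(k)) {
      spec <- config$datasets[[di]]
      tasks <- if (is.null(spec$tasks)) "other" else spec$tasks
      for (ni in seq_len(per[di])) {
        id <- sprintf("%s_%03d", spec$id, ni)
        n_sent <- .sample_range(config$sentences_per_narrative)
        cls_seq <- sample(names(spec$weights), n_sent, replace = TRUE,
                          prob = spec$weights)
        seg_texts <- character()
        seg_cats <- character()
        for (si in seq_len(n_sent)) {
          w <- .sample_range(config$words_per_segment)
          parts <- .sentence_parts(cls_seq[si], w)
          texts <- vapply(parts, function(p) {
            .fragment(p[1], as.integer(p[2]))
          }, character(1))
          term <- sample(c(".", "!", "?"), 1L, prob = c(0.8, 0.1, 0.1))
          texts[length(texts)] <- paste0(texts[length(texts)], term)
          seg_texts <- c(seg_texts, texts)
          seg_cats <- c(seg_cats, vapply(parts, `[`, character(1), 1L))
        }
        wc <- word_count(seg_texts)
        details <- pmax(
          0,
          round(config$details_per_word_rate * wc +
                stats::rnorm(length(wc), 0, config$proxy_noise_sd))
        )
        nar_rows[[length(nar_rows) + 1L]] <- tibble::tibble(
          narrative_id = id,
          dataset_id = spec$id,
          task = tasks[(ni - 1L) %% length(tasks) + 1L],
          text = paste(seg_texts, collapse = " ")
        )
        seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
          narrative_id = id,
          segment_index = seq_along(seg_texts) - 1L,
          text = seg_texts,
          category = seg_cats,
          detail_count = as.integer(details)
        )
      }
    }
    annotated_corpus(dplyr::bind_rows(nar_rows), dplyr::bind_rows(seg_rows))
  })
  if (config$punctuation_dropout > 0) {
    corpus <- apply_punctuation_dropout(
      corpus, config$punctuation_dropout, config$seed + 777L
    )
  }
  corpus
}

#' Delete sentence terminators at random
#'
#' Emulates transcripts typed with little punctuation: each
#' sentence-terminal punctuation mark (a segment-final `.`, `!` or `?`) is
#' deleted independently with probability `p`. Word counts, span categories
#' and detail counts are untouched; only the terminators disappear, so the
#' sentence splitter merges the affected sentences downstream.
#'
#' @param annotations an `ai_annotations` object.
#' @param p deletion probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the degraded `ai_annotations` object.
#' @export
apply_punctuation_dropout <- function(annotations, p, seed) {
  stopifnot(inherits(annotations, "ai_annotations"))
  if (p < 0 || p > 1) stopf("`p` must lie in [0, 1]")
  seg <- annotations$segments
  terminal <- grepl("[.!?]$", seg$text)
  drop <- with_seed(seed, stats::runif(nrow(seg)) < p) & terminal
  seg$text[drop] <- sub("[.!?]+$", "", seg$text[drop])
  nar <- annotations$narratives
  nar$text <- vapply(nar$narrative_id, function(id) {
    paste(seg$text[seg$narrative_id == id], collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  annotated_corpus(
    nar,
    seg[, c("narrative_id", "segment_index", "text", "category",
            "detail_count")]
  )
}

#' Permute span categories across a corpus
#'
#' Null-model construction: the internal/external category labels of all
#' segments are randomly permuted across the corpus while text, word counts
#' and detail counts stay attached to their segments. Used to build truth
#' vectors statistically independent of any prediction derived from the
#' original labels.
#'
#' @param annotations an `ai_annotations` object.
#' @param seed integer seed.
#' @return an `ai_annotations` object with permuted categories.
#' @export
shuffle_labels <- function(annotations, seed) {
  stopifnot(inherits(annotations, "ai_annotations"))
  seg <- annotations$segments
  perm <- with_seed(seed, sample.int(nrow(seg)))
  seg$category <- seg$category[perm]
  annotated_corpus(
    annotations$narratives,
    seg[, c("narrative_id", "segment_index", "text", "category",
            "detail_count")]
  )
}
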