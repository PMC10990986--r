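#' The four internal-content proportion classes
#'
#' Sentences are labeled by how much of their content is internal
#' (episodic): none, half, three quarters, or all. The four representative
#' fractions are the cluster centers observed in sentence-level internal
#' proportions; they are fixed constants of the method, not tunable.
#'
#' @return tibble with columns `label` (`P0`, `P50`, `P75`, `P100`) and
#'   `fraction` (0, 0.5, 0.75, 1).
#' @export
proportion_classes <- function() {
  tibble::tibble(
    label = c("P0", "P50", "P75", "P100"),
    fraction = c(0, 0.5, 0.75, 1)
  )
}

#' Proportion-class factor levels in increasing internal order
#' @return character vector `c("P0","P50","P75","P100")`.
#' @export
class_levels <- function() proportion_classes()$label

#' Representative internal fraction of a class
#'
#' @param cls character vector or factor of class labels.
#' @return numeric vector of representative fractions.
#' @export
class_fraction <- function(cls) {
  pc <- proportion_classes()
  idx <- match(as.character(cls), pc$label)
  if (anyNA(idx)) {
    stopf("unknown class label(s): %s",
          paste(unique(as.character(cls)[is.na(idx)]), collapse = ", "))
  }
  pc$fraction[idx]
}

#' Bin an internal fraction into its proportion class
#'
#' Assigns each fraction in `[0, 1]` to the nearest of the four class
#' centers {0, 0.5, 0.75, 1}; a fraction equidistant between two centers
#' goes to the higher (more internal) class. There is no 25% class, so
#' external-heavy mixed sentences map to `P0` or `P50` by nearness — a
#' deliberate consequence of the four-class label set.
#'
#' @param fraction numeric vector in `[0, 1]`.
#' @return factor with levels `P0 < P50 < P75 < P100`.
#' @examples
#' bin_fraction(c(0.6, 0.25, 1))
#' @export
bin_fraction <- function(fraction) {
  if (!is.numeric(fraction)) stopf("`fraction` must be numeric")
  if (anyNA(fraction) || any(fraction < 0 | fraction > 1)) {
    stopf("`fraction` values must lie in [0, 1]")
  }
  pc <- proportion_classes()
  idx <- vapply(fraction, function(f) {
    d <- abs(f - pc$fraction)
    max(which(d <= min(d) + 1e-15))  # ties to the higher class
  }, integer(1))
  factor(pc$label[idx], levels = pc$label, ordered = TRUE)
}

# Align a narrative's sentences with its annotation spans at word
# resolution. Each word of the narrative inherits the category of the span
# it falls in; a sentence's internal fraction is the share of its words
# that are internal. A span crossing a sentence boundary contributes its
# detail count to each side prorated by word overlap, rounded half-up.
.align_narrative <- function(text, segments, abbreviations) {
  seg_words <- segments$word_count
  word_cat <- rep(segments$category, seg_words)
  word_seg <- rep(seq_len(nrow(segments)), seg_words)
  sents <- split_sentences(text, abbreviations)
  if (nrow(sents) == 0L) return(NULL)
  offsets <- cumsum(c(0L, sents$word_count))
  if (offsets[length(offsets)] != length(word_cat)) {
    stopf("sentence words (%d) do not align with segment words (%d)",
          offsets[length(offsets)], length(word_cat))
  }
  res <- lapply(seq_len(nrow(sents)), function(i) {
    rng <- (offsets[i] + 1L):offsets[i + 1L]
    cats <- word_cat[rng]
    segs <- word_seg[rng]
    overlap <- table(segs)
    seg_ids <- as.integer(names(overlap))
    full <- as.integer(overlap) == seg_words[seg_ids]
    contrib <- ifelse(
      full,
      segments$detail_count[seg_ids],
      round_half_up(segments$detail_count[seg_ids] *
                    as.integer(overlap) / seg_words[seg_ids])
    )
    internal_seg <- segments$category[seg_ids] == "internal"
    c(
      internal_words = sum(cats == "internal"),
      detail_internal = sum(contrib[internal_seg]),
      detail_external = sum(contrib[!internal_seg])
    )
  })
  m <- do.call(rbind, res)
  sents$internal_words <- as.integer(m[, "internal_words"])
  sents$internal_fraction <- sents$internal_words / sents$word_count
  sents$detail_internal <- as.numeric(m[, "detail_internal"])
  sents$detail_external <- as.numeric(m[, "detail_external"])
  sents$detail_count <- sents$detail_internal + sents$detail_external
  sents
}

#' Sentence-level view of an annotated corpus
#'
#' Splits every annotated narrative into sentences and attributes the span
#' annotations to them: each sentence gets its true internal-word count and
#' internal fraction (exact, from word overlap with the spans) and its
#' manual detail count (spans fully inside a sentence contribute their whole
#' count; a span crossing a sentence boundary is prorated by word overlap
#' and rounded half-up on each side).
#'
#' @param annotations an `ai_annotations` object.
#' @param abbreviations passed to [split_sentences()].
#' @return tibble with one row per sentence: `narrative_id`, `index`,
#'   `text`, `word_count`, `internal_words`, `internal_fraction`,
#'   `detail_internal`, `detail_external`, `detail_count`.
#' @export
sentence_annotations <- function(annotations,
                                 abbreviations = ai_abbreviations()) {
  stopifnot(inherits(annotations, "ai_annotations"))
  nar <- annotations$narratives
  parts <- lapply(seq_len(nrow(nar)), function(i) {
    id <- nar$narrative_id[i]
    seg <- annotations$segments[annotations$segments$narrative_id == id, ,
                                drop = FALSE]
    s <- .align_narrative(nar$text[i], seg, abbreviations)
    if (is.null(s)) return(NULL)
    s$narrative_id <- id
    s
  })
  out <- dplyr::bind_rows(parts)
  out[, c("narrative_id", "index", "text", "word_count", "internal_words",
          "internal_fraction", "detail_internal", "detail_external",
          "detail_count")]
}

#' Internal fraction of one sentence of an annotated narrative
#'
#' Convenience wrapper around the corpus-level alignment: the fraction of
#' the sentence's words that fall in internal spans. The sentence must come
#' from [split_sentences()] applied to the narrative's text (it is located
#' by `narrative_id` and `index`).
#'
#' @param sentence one-row tibble with `narrative_id` and `index`.
#' @param annotations an `ai_annotations` object containing that narrative.
#' @return a single numeric fraction in `[0, 1]`.
#' @export
compute_internal_fraction <- function(sentence, annotations) {
  stopifnot(is.data.frame(sentence), nrow(sentence) == 1L)
  tab <- sentence_annotations(annotations)
  row <- tab[tab$narrative_id == sentence$narrative_id &
             tab$index == sentence$index, , drop = FALSE]
  if (nrow(row) == 0L) {
    stopf("sentence (%s, %d) not found in annotations",
          sentence$narrative_id, sentence$index)
  }
  if (row$word_count == 0L) stopf("zero-word sentence has no fraction")
  row$internal_fraction
}

#' Label sentences with their proportion class
#'
#' @param sentences sentence-annotation tibble from [sentence_annotations()]
#'   (zero-word sentences must have been excluded upstream).
#' @return the same tibble with a `cls` factor column added.
#' @export
label_sentences <- function(sentences) {
  stopifnot("internal_fraction" %in% names(sentences))
  if (any(sentences$word_count == 0L)) {
    stopf("zero-word sentences cannot be labeled; filter them first")
  }
  sentences$cls <- bin_fraction(sentences$internal_fraction)
  sentences
}

#' Balance classes by upsampling with replacement
#'
#' Training sets are modified so every proportion class has the same number
#' of sentences: the largest class count is found, and every other class is
#' topped up by sampling from itself with replacement. Without this, a model
#' could score well simply by exploiting the base rate of internal content.
#' All original rows are retained; every added row is a duplicate of an
#' existing row of the same class. Per-class draws are made in fixed label
#' order (`P0`, `P50`, `P75`, `P100`) from a single seeded stream, so a seed
#' fully determines the result.
#'
#' @param labeled tibble with a `cls` column (see [label_sentences()]).
#' @param seed integer seed for the sampling stream.
#' @param classes the class labels that must be present and balanced;
#'   defaults to all four. A class in `classes` with no sentences is an
#'   error (there is nothing to upsample from).
#' @return the balanced tibble: original rows first (input order), then the
#'   upsampled duplicates grouped by class.
#' @export
balance_classes <- function(labeled, seed, classes = class_levels()) {
  stopifnot("cls" %in% names(labeled))
  cls <- factor(as.character(labeled$cls), levels = classes)
  if (anyNA(cls)) {
    stopf("labeled data contain classes outside `classes`: %s",
          paste(setdiff(unique(as.character(labeled$cls)), classes),
                collapse = ", "))
  }
  counts <- table(cls)
  empty <- names(counts)[counts == 0L]
  if (length(empty) > 0L) {
    stopf("cannot upsample empty class(es): %s",
          paste(empty, collapse = ", "))
  }
  target <- max(counts)
  extra_idx <- with_seed(seed, {
    unlist(lapply(classes, function(lv) {
      pool <- which(cls == lv)
      need <- target - length(pool)
      if (need == 0L) return(integer())
      pool[sample.int(length(pool), need, replace = TRUE)]
    }))
  })
  dplyr::bind_rows(labeled, labeled[extra_idx, , drop = FALSE])
}
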