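test_that("bin_fraction maps to the nearest class center, ties upward", {
  expect_equal(as.character(bin_fraction(0.5)), "P50")
  expect_equal(as.character(bin_fraction(0.6)), "P50")   # |0.6-0.5| < |0.6-0.75|
  expect_equal(as.character(bin_fraction(0.25)), "P50")  # midpoint tie -> higher
  expect_equal(as.character(bin_fraction(0.625)), "P75") # midpoint tie -> higher
  expect_equal(as.character(bin_fraction(0.875)), "P100")
  # idempotent on the four centers
  pc <- proportion_classes()
  expect_equal(as.character(bin_fraction(pc$fraction)), pc$label)
  expect_error(bin_fraction(1.2), "\\[0, 1\\]")
  expect_error(bin_fraction(-0.1), "\\[0, 1\\]")
})

test_that("internal fractions follow word overlap with annotation spans", {
  ann <- tiny_annotations()
  sent <- sentence_annotations(ann)
  n1 <- sent[sent$narrative_id == "n1", ]
  expect_equal(n1$internal_fraction, c(1, 0))
  expect_equal(n1$word_count, c(6L, 4L))

  # single-sentence wrapper agrees with the bulk table
  expect_equal(
    compute_internal_fraction(
      tibble::tibble(narrative_id = "n1", index = 0L), ann
    ),
    1
  )
  expect_error(
    compute_internal_fraction(
      tibble::tibble(narrative_id = "n1", index = 9L), ann
    ),
    "not found"
  )
})

test_that("a span crossing a sentence boundary is prorated half-up", {
  # seg1 (internal, 3 details) spans tokens "aa bb cc. dd ee": 3 words in
  # the first sentence, 2 in the second; seg2 (external, 1 detail) is fully
  # in the second sentence.
  nar <- tibble::tibble(narrative_id = "x", dataset_id = "d", task = "t",
                        text = "aa bb cc. dd ee ff gg.")
  seg <- tibble::tibble(
    narrative_id = "x", segment_index = 0:1,
    text = c("aa bb cc. dd ee", "ff gg."),
    category = c("internal", "external"),
    detail_count = c(3L, 1L)
  )
  sent <- sentence_annotations(annotated_corpus(nar, seg))
  expect_equal(nrow(sent), 2L)
  # sentence 1: round_half_up(3 * 3/5) = 2 internal details, all words internal
  expect_equal(sent$detail_internal, c(2, 1))  # round_half_up(3 * 2/5) = 1
  expect_equal(sent$detail_external, c(0, 1))
  expect_equal(sent$internal_fraction, c(1, 2 / 4))
})

test_that("fractions of a mixed sentence reflect its word split", {
  # one sentence: 6 internal words + 2 external words -> 0.75
  nar <- tibble::tibble(narrative_id = "m", dataset_id = "d", task = "t",
                        text = "a b c d e f g h.")
  seg <- tibble::tibble(
    narrative_id = "m", segment_index = 0:1,
    text = c("a b c d e f", "g h."),
    category = c("internal", "external"),
    detail_count = c(2L, 1L)
  )
  sent <- sentence_annotations(annotated_corpus(nar, seg))
  expect_equal(sent$internal_fraction, 0.75)
  expect_equal(as.character(label_sentences(sent)$cls), "P75")
})

test_that("balance_classes upsamples with replacement to the max count", {
  labeled <- tibble::tibble(
    text = paste("sentence", 1:4),
    cls = factor(c("P0", "P0", "P0", "P100"),
                 levels = class_levels(), ordered = TRUE)
  )
  out <- balance_classes(labeled, seed = 1, classes = c("P0", "P100"))
  expect_equal(nrow(out), 6L)
  counts <- table(as.character(out$cls))
  expect_equal(as.integer(counts[c("P0", "P100")]), c(3L, 3L))
  # originals all retained, in order, ahead of the duplicates
  expect_identical(out[1:4, ], labeled)
  # every addition duplicates an existing member of its class
  added <- out[5:6, ]
  expect_true(all(added$text %in% labeled$text[labeled$cls == "P100"]))

  # already balanced input is returned unchanged
  eq <- labeled[c(1, 4), ]
  expect_identical(balance_classes(eq, seed = 1, classes = c("P0", "P100")),
                   eq)
  # empty class cannot be upsampled
  expect_error(balance_classes(labeled, seed = 1), "empty class.*P50")
})

test_that("balancing is deterministic in the seed and preserves identities", {
  corpus <- generate_corpus(generator_config(n_narratives = 30, seed = 5))
  labeled <- label_sentences(sentence_annotations(corpus))
  a <- balance_classes(labeled, seed = 11)
  b <- balance_classes(labeled, seed = 11)
  expect_identical(a, b)
  counts <- table(as.character(a$cls))
  expect_equal(length(unique(counts)), 1L)
  expect_equal(sum(counts), 4L * max(table(as.character(labeled$cls))))
  # the distinct sentence identities are unchanged
  key <- function(d) sort(unique(paste(d$narrative_id, d$index)))
  expect_identical(key(a), key(labeled))
  # a different seed may differ only in which duplicates were drawn
  c_ <- balance_classes(labeled, seed = 12)
  expect_identical(c_[seq_len(nrow(labeled)), ], labeled)
})
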