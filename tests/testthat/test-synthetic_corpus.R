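test_that("generated corpora satisfy the annotation invariants", {
  corpus <- generate_corpus(generator_config(n_narratives = 10, seed = 1))
  expect_s3_class(corpus, "ai_annotations")
  expect_equal(nrow(corpus$narratives), 10L)
  tot <- annotation_totals(corpus)
  seg <- corpus$segments
  for (id in tot$narrative_id) {
    s <- seg[seg$narrative_id == id, ]
    expect_equal(tot$internal_words[tot$narrative_id == id],
                 sum(s$word_count[s$category == "internal"]))
    expect_equal(tot$internal_details[tot$narrative_id == id],
                 sum(s$detail_count[s$category == "internal"]))
  }
  # all true sentence fractions sit on the four class centers
  sent <- sentence_annotations(corpus)
  expect_true(all(sent$internal_fraction %in% c(0, 0.5, 0.75, 1)))
})

test_that("without dropout every generated sentence is recovered by the splitter", {
  corpus <- generate_corpus(generator_config(n_narratives = 15, seed = 2))
  seg <- corpus$segments
  for (i in seq_len(nrow(corpus$narratives))) {
    id <- corpus$narratives$narrative_id[i]
    n_generated <- sum(grepl("[.!?]$", seg$text[seg$narrative_id == id]))
    expect_equal(nrow(split_sentences(corpus$narratives$text[i])),
                 n_generated)
  }
})

test_that("generation is a pure function of the config", {
  cfg <- generator_config(n_narratives = 15, seed = 6)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$narratives, b$narratives)
  expect_identical(a$segments, b$segments)
  c_ <- generate_corpus(generator_config(n_narratives = 15, seed = 7))
  expect_false(identical(a$narratives$text, c_$narratives$text))
})

test_that("class mixing weights are honored within sampling error", {
  cfg <- generator_config(n_narratives = 150, seed = 10)
  sent <- label_sentences(sentence_annotations(generate_corpus(cfg)))
  nar <- generate_corpus(cfg)$narratives
  sent$dataset_id <- nar$dataset_id[match(sent$narrative_id,
                                          nar$narrative_id)]
  sim <- sent[sent$dataset_id == "simulation", ]  # uniform weights
  props <- table(as.character(sim$cls)) / nrow(sim)
  # 99% binomial CI half-width at n ~ 350 is about 0.06
  expect_true(all(abs(props - 0.25) < 0.08))
})

test_that("dropout deletes terminators but preserves content and truth", {
  base <- generator_config(n_narratives = 30, seed = 12)
  deg_cfg <- generator_config(n_narratives = 30, seed = 12,
                              punctuation_dropout = 0.8)
  clean <- generate_corpus(base)
  deg <- generate_corpus(deg_cfg)
  strip_term <- function(x) gsub("[.!?]", "", x)
  expect_identical(strip_term(deg$narratives$text),
                   strip_term(clean$narratives$text))
  expect_identical(deg$segments$category, clean$segments$category)
  expect_identical(deg$segments$detail_count, clean$segments$detail_count)
  expect_identical(deg$segments$word_count, clean$segments$word_count)
  n_term <- function(corpus) sum(grepl("[.!?]$", corpus$segments$text))
  expect_lt(n_term(deg), n_term(clean))
})

test_that("shuffle_labels permutes categories and nothing else", {
  corpus <- generate_corpus(generator_config(n_narratives = 20, seed = 13))
  sh <- shuffle_labels(corpus, seed = 99)
  expect_identical(sh$segments$text, corpus$segments$text)
  expect_identical(sh$segments$word_count, corpus$segments$word_count)
  expect_identical(sort(sh$segments$category),
                   sort(corpus$segments$category))
  expect_false(identical(sh$segments$category, corpus$segments$category))
  expect_identical(shuffle_labels(corpus, seed = 99)$segments$category,
                   sh$segments$category)
})

test_that("generated data pushed through the oracle pipeline reproduce truth", {
  corpus <- generate_corpus(generator_config(n_narratives = 30, seed = 20))
  truth <- annotation_totals(corpus)
  sc <- score_corpus(corpus$narratives, oracle_classifier(corpus))
  m <- dplyr::inner_join(sc, truth, by = "narrative_id")
  expect_equal(m$predicted_internal_words, m$internal_words)
  expect_equal(m$predicted_external_words, m$external_words)
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(n_narratives = 0), "positive")
  expect_error(
    generator_config(datasets = list(list(id = "x",
                                          weights = c(0.5, 0.5, 0.5, 0.5)))),
    "summing to 1"
  )
  expect_error(generator_config(punctuation_dropout = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(words_per_segment = c(5, 2)), "min <= max")
})
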