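test_that("quadrant correlations match the textbook computation", {
  set.seed(99)
  n <- 40
  truth <- tibble::tibble(
    narrative_id = as.character(1:n),
    internal_details = rpois(n, 20) + rnorm(n),
    external_details = rpois(n, 10) + rnorm(n)
  )
  scores <- tibble::tibble(
    narrative_id = as.character(1:n),
    predicted_internal_words = truth$internal_details * 8 + rnorm(n, 0, 10),
    predicted_external_words = truth$external_details * 7 + rnorm(n, 0, 10),
    total_words = 1L
  )
  rep <- quadrant_report(scores, truth)
  oracle <- pearson_manual(truth$internal_details,
                           scores$predicted_internal_words)
  expect_equal(quadrant_r(rep, "int_int"), oracle$r, tolerance = 1e-12)
  expect_equal(rep$p[rep$quadrant == "int_int"], oracle$p, tolerance = 1e-12)
  oracle_x <- pearson_manual(truth$external_details,
                             scores$predicted_internal_words)
  expect_equal(quadrant_r(rep, "ext_int"), oracle_x$r, tolerance = 1e-12)
  expect_equal(rep$r_squared, rep$r^2, tolerance = 1e-12)
})

test_that("perfect and linear predictions give r = 1", {
  truth <- tibble::tibble(
    narrative_id = letters[1:4],
    internal_details = c(1, 2, 3, 4),
    external_details = c(4, 1, 3, 2)
  )
  scores <- tibble::tibble(
    narrative_id = letters[1:4],
    predicted_internal_words = c(2, 4, 6, 8),  # exact linear map
    predicted_external_words = truth$external_details,
    total_words = 1L
  )
  rep <- quadrant_report(scores, truth)
  expect_equal(quadrant_r(rep, "int_int"), 1, tolerance = 1e-12)
  expect_equal(quadrant_r(rep, "ext_ext"), 1, tolerance = 1e-12)
})

test_that("quadrant_report rejects bad input and flags degenerate columns", {
  truth <- tibble::tibble(narrative_id = c("a", "b", "c"),
                          internal_details = c(1, 2, 3),
                          external_details = c(2, 2, 2))
  scores <- tibble::tibble(narrative_id = c("a", "b", "z"),
                           predicted_internal_words = 1:3,
                           predicted_external_words = 3:1,
                           total_words = 4L)
  expect_error(quadrant_report(scores, truth), "align")

  scores$narrative_id <- c("a", "b", "c")
  rep <- quadrant_report(scores, truth)
  # constant external details -> the two external-truth quadrants undefined
  expect_equal(rep$status[rep$quadrant == "ext_ext"], "undefined")
  expect_equal(rep$status[rep$quadrant == "ext_int"], "undefined")
  expect_equal(rep$status[rep$quadrant == "int_int"], "ok")
  expect_error(quadrant_report(scores[1:2, ], truth[1:2, ]), "n >= 3")
})

test_that("label-shuffled truth is uncorrelated with oracle predictions", {
  # constant narrative length removes the shared length factor, so the
  # permuted labels make truth statistically independent of predictions
  cfg <- generator_config(
    n_narratives = 500,
    datasets = list(list(id = "null",
                         weights = c(P0 = 1/3, P50 = 1/3, P75 = 0, P100 = 1/3),
                         tasks = "memory")),
    sentences_per_narrative = c(6L, 6L),
    words_per_segment = c(4L, 4L),
    seed = 5
  )
  corpus <- generate_corpus(cfg)
  sc <- score_corpus(corpus$narratives, oracle_classifier(corpus))
  truth <- annotation_totals(shuffle_labels(corpus, seed = 6))
  rep <- quadrant_report(sc, truth)
  expect_true(all(abs(rep$r) < 0.15))
})

test_that("proxy validation recovers exact and degenerate relations", {
  # internal words exactly 10x internal details -> r_internal = 1; external
  # details constant at 0 across the group -> undefined, with a warning
  nar <- tibble::tibble(
    narrative_id = c("p1", "p2", "p3"),
    dataset_id = "lin", task = "t",
    text = c(paste(rep("w", 10), collapse = " "),
             paste(rep("w", 20), collapse = " "),
             paste(rep("w", 30), collapse = " "))
  )
  seg <- tibble::tibble(
    narrative_id = nar$narrative_id, segment_index = 0L,
    text = nar$text, category = "internal", detail_count = c(1L, 2L, 3L)
  )
  expect_warning(pv <- proxy_validation(annotated_corpus(nar, seg)),
                 "undefined")
  expect_equal(pv$per_group$r_internal, 1, tolerance = 1e-12)
  expect_equal(pv$per_group$status_external, "undefined")

  # a two-narrative group cannot define r
  expect_warning(pv2 <- proxy_validation(
    annotated_corpus(nar[1:2, ], seg[1:2, ])
  ), "undefined")
  expect_equal(pv2$per_group$status_internal, "undefined")
})

test_that("generator proxy correlations land in the configured band", {
  corpus <- generate_corpus(generator_config(n_narratives = 200, seed = 3))
  pv <- proxy_validation(corpus)
  expect_true(all(pv$per_group$status_internal == "ok"))
  expect_true(all(pv$per_group$r_internal >= 0.86 &
                  pv$per_group$r_internal <= 0.98))
  # cross-check one group with the independent routine
  tot <- annotation_totals(corpus)
  g <- tot[tot$dataset_id == "memories", ]
  expect_equal(pv$per_group$r_internal[pv$per_group$group == "memories"],
               pearson_manual(g$internal_details, g$internal_words)$r,
               tolerance = 1e-12)
})

test_that("leave-one-dataset-out keeps folds isolated and reports subgroups", {
  corpus <- generate_corpus(generator_config(n_narratives = 60, seed = 17))
  res <- leave_one_dataset_out(corpus, train_config(seed = 17))
  expect_s3_class(res, "ai_loco_result")
  expect_equal(length(res), 3L)
  held <- vapply(res, `[[`, character(1), "held_out")
  expect_setequal(held, c("memories", "simulation", "writing"))
  for (fold in res) {
    held_ids <- corpus$narratives$narrative_id[
      corpus$narratives$dataset_id == fold$held_out]
    expect_length(intersect(fold$manifest$trained_narrative_ids, held_ids), 0)
  }
  # the two-task dataset yields one report per age-group-style subgroup
  sim <- res[[which(held == "simulation")]]
  expect_setequal(names(sim$reports), c("young", "old"))
  mem <- res[[which(held == "memories")]]
  expect_equal(names(mem$reports), "all")
})

test_that("protected datasets are never trained on but still evaluated", {
  corpus <- generate_corpus(generator_config(n_narratives = 60, seed = 18))
  res <- leave_one_dataset_out(corpus, train_config(seed = 18),
                               protected = "writing")
  held <- vapply(res, `[[`, character(1), "held_out")
  expect_setequal(held, c("memories", "simulation", "writing"))
  prot <- res[[which(held == "writing")]]
  expect_true(prot$protected)
  expect_equal(prot$protected_model, "all")
  writing_ids <- corpus$narratives$narrative_id[
    corpus$narratives$dataset_id == "writing"]
  for (fold in res) {
    expect_length(intersect(fold$manifest$trained_narrative_ids,
                            writing_ids), 0)
  }
  expect_error(
    leave_one_dataset_out(corpus, train_config(seed = 18),
                          protected = c("memories", "simulation", "writing")),
    "protected"
  )
})

test_that("evaluation results serialize to JSON records", {
  corpus <- generate_corpus(generator_config(n_narratives = 45, seed = 19))
  res <- leave_one_dataset_out(corpus, train_config(seed = 19),
                               by_task = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_loco_report(res, path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(rec), 3L)
  expect_true(all(c("held_out", "subgroup", "r_int_int", "p_int_int",
                    "r2_ext_ext") %in% names(rec)))
})
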