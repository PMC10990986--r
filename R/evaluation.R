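# Pearson r with a two-sided p-value from the t transform (n - 2 df).
# Degenerate inputs (n < 3 or a constant vector) yield an explicit
# "undefined" status rather than NaN or a silent zero.
.pearson <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stopf("vectors differ in length (%d vs %d)", n,
                            length(y))
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                          n = n, status = "undefined"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  tibble::tibble(r = r, r_squared = r^2, p = ct$p.value, n = n,
                 status = "ok")
}

#' Validate word counts as a proxy for manual detail counts
#'
#' For each dataset, the Pearson correlation between the manual internal
#' detail count and the internal word count across narratives (and likewise
#' for external), plus the range and mean across datasets. High
#' correlations justify scoring content in words rather than segmenting it
#' into individual details.
#'
#' @param annotations an `ai_annotations` object.
#' @param group_by grouping column of the narrative table (default
#'   `"dataset_id"`).
#' @return an object of class `ai_proxy_report`: list with `per_group`
#'   (tibble of r per group and category) and `summary` (min/max/mean per
#'   category over defined groups).
#' @export
proxy_validation <- function(annotations, group_by = "dataset_id") {
  tot <- annotation_totals(annotations)
  if (!group_by %in% names(tot)) stopf("unknown grouping column '%s'",
                                       group_by)
  groups <- unique(tot[[group_by]])
  rows <- lapply(groups, function(g) {
    sub <- tot[tot[[group_by]] == g, , drop = FALSE]
    ri <- .pearson(sub$internal_details, sub$internal_words)
    re <- .pearson(sub$external_details, sub$external_words)
    if (ri$status == "undefined" || re$status == "undefined") {
      warnf("proxy correlation undefined for group '%s' (n=%d)", g,
            nrow(sub))
    }
    tibble::tibble(
      group = g, n = nrow(sub),
      r_internal = ri$r, r_external = re$r,
      status_internal = ri$status, status_external = re$status
    )
  })
  per_group <- dplyr::bind_rows(rows)
  summarize_cat <- function(r, status) {
    ok <- status == "ok"
    if (!any(ok)) return(list(min = NA_real_, max = NA_real_,
                              mean = NA_real_))
    list(min = min(r[ok]), max = max(r[ok]), mean = mean(r[ok]))
  }
  structure(
    list(
      per_group = per_group,
      summary = list(
        internal = summarize_cat(per_group$r_internal,
                                 per_group$status_internal),
        external = summarize_cat(per_group$r_external,
                                 per_group$status_external)
      )
    ),
    class = "ai_proxy_report"
  )
}

#' @export
print.ai_proxy_report <- function(x, ...) {
  cat("<ai_proxy_report>\n")
  print(x$per_group)
  s <- x$summary
  cat(sprintf("internal: r in [%.3f, %.3f], mean %.3f\n",
              s$internal$min, s$internal$max, s$internal$mean))
  cat(sprintf("external: r in [%.3f, %.3f], mean %.3f\n",
              s$external$min, s$external$max, s$external$mean))
  invisible(x)
}

#' Four-quadrant validation of automated scores
#'
#' Correlates predicted internal/external content with manual
#' internal/external detail counts in the 2x2 design: an accurate,
#' non-confused scorer shows high `r_int_int` (internal details vs
#' predicted internal words) and `r_ext_ext`, and near-zero cross
#' correlations `r_int_ext` (internal details vs predicted external — how
#' much internal content is misclassified as external) and `r_ext_int`.
#' P-values are two-sided via the t transform with n - 2 degrees of
#' freedom.
#'
#' @param scores score tibble (see [score_corpus()]).
#' @param truth tibble with `narrative_id`, `internal_details`,
#'   `external_details`; ids must match `scores` one to one.
#' @return an object of class `ai_quadrant_report`: tibble with one row per
#'   quadrant (`quadrant`, `r`, `r_squared`, `p`, `n`, `status`).
#' @export
quadrant_report <- function(scores, truth) {
  need_s <- c("narrative_id", "predicted_internal_words",
              "predicted_external_words")
  need_t <- c("narrative_id", "internal_details", "external_details")
  for (col in need_s) {
    if (!col %in% names(scores)) stopf("scores lack column '%s'", col)
  }
  for (col in need_t) {
    if (!col %in% names(truth)) stopf("truth lacks column '%s'", col)
  }
  if (anyDuplicated(scores$narrative_id) || anyDuplicated(truth$narrative_id)) {
    stopf("narrative_id must be unique in scores and truth")
  }
  if (!setequal(scores$narrative_id, truth$narrative_id)) {
    stopf("scores and truth narrative ids do not align")
  }
  m <- dplyr::inner_join(scores, truth, by = "narrative_id")
  if (nrow(m) < 3L) stopf("quadrant report requires n >= 3 narratives")
  quadrants <- list(
    int_int = c("internal_details", "predicted_internal_words"),
    ext_ext = c("external_details", "predicted_external_words"),
    int_ext = c("internal_details", "predicted_external_words"),
    ext_int = c("external_details", "predicted_internal_words")
  )
  rows <- lapply(names(quadrants), function(q) {
    v <- quadrants[[q]]
    res <- .pearson(m[[v[1]]], m[[v[2]]])
    res$quadrant <- q
    res
  })
  out <- dplyr::bind_rows(rows)[, c("quadrant", "r", "r_squared", "p", "n",
                                    "status")]
  class(out) <- c("ai_quadrant_report", class(out))
  out
}

#' @export
print.ai_quadrant_report <- function(x, ...) {
  cat("<ai_quadrant_report>\n")
  df <- as.data.frame(x)
  df$r <- round(df$r, 3)
  df$r_squared <- round(df$r_squared, 3)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# extract one quadrant's r from a report
quadrant_r <- function(report, quadrant) {
  report$r[report$quadrant == quadrant]
}

# Training-pool preparation shared by LOCO folds: sentence view, >8-detail
# filter, class labels, upsampling to balance.
.prepare_training <- function(annotations, balance_seed, max_details) {
  sent <- sentence_annotations(annotations)
  sent <- sent[sent$word_count > 0L, , drop = FALSE]
  filt <- filter_long_sentences(sent, max_details)
  labeled <- label_sentences(filt$retained)
  present <- intersect(class_levels(), unique(as.character(labeled$cls)))
  balance_classes(labeled, seed = balance_seed, classes = present)
}

# Held-out evaluation set preparation: the same filter is applied and the
# truth detail counts are decremented by the details removed with dropped
# sentences, mirroring how validation counts are updated during data
# preparation.
.prepare_eval <- function(annotations, max_details) {
  sent <- sentence_annotations(annotations)
  sent <- sent[sent$word_count > 0L, , drop = FALSE]
  filt <- filter_long_sentences(sent, max_details)
  truth <- annotation_totals(annotations)
  adj <- filt$adjustments
  if (nrow(adj) > 0L) {
    truth <- dplyr::left_join(truth, adj, by = "narrative_id")
    for (col in c("internal_details_removed", "external_details_removed")) {
      truth[[col]][is.na(truth[[col]])] <- 0
    }
    truth$internal_details <- truth$internal_details -
      truth$internal_details_removed
    truth$external_details <- truth$external_details -
      truth$external_details_removed
  }
  list(sentences = filt$retained,
       truth = truth[, c("narrative_id", "dataset_id", "task",
                         "internal_details", "external_details")])
}

.score_eval <- function(prep, model, mode) {
  scored <- .score_sentence_table(prep$sentences, model, mode)
  out <- dplyr::left_join(
    prep$truth[, "narrative_id", drop = FALSE], scored, by = "narrative_id"
  )
  for (col in c("predicted_internal_words", "predicted_external_words",
                "total_words")) {
    out[[col]][is.na(out[[col]])] <- 0
  }
  out
}

.report_subgroups <- function(scores, truth, by_task) {
  tasks <- unique(truth$task)
  if (!by_task || length(tasks) <= 1L) {
    return(list(all = quadrant_report(scores, truth)))
  }
  reports <- lapply(tasks, function(tk) {
    ids <- truth$narrative_id[truth$task == tk]
    quadrant_report(scores[scores$narrative_id %in% ids, , drop = FALSE],
                    truth[truth$task == tk, , drop = FALSE])
  })
  names(reports) <- tasks
  reports
}

#' Leave-one-dataset-out cross-validation
#'
#' Generalization is assessed at the level of whole studies: each
#' non-protected dataset is held out in turn, the classifier is trained on
#' the remaining non-protected datasets (long-sentence filter, labeling and
#' class balancing applied to the training pool only), the held-out
#' narratives are scored, and a four-quadrant report is produced — per task
#' subgroup when the held-out dataset spans several tasks. Protected
#' datasets (e.g. tasks scored with a different procedure) are never
#' trained on; they are evaluated against a model trained on all
#' non-protected data (`protected_model = "all"`, the default) or against
#' each fold's model (`"fold"`).
#'
#' The held-out sets get the same long-sentence filter as the training
#' data, with their truth detail counts decremented accordingly.
#'
#' @param annotations an `ai_annotations` object spanning >= 2 non-protected
#'   datasets.
#' @param config an [train_config()] object.
#' @param protected dataset ids never used for training.
#' @param balance_seed seed for class balancing (default: the config seed).
#' @param max_details long-sentence filter threshold (default 8).
#' @param by_task emit one report per task subgroup of a held-out dataset
#'   (default `TRUE`).
#' @param protected_model `"all"` or `"fold"` (see above).
#' @param mode scoring mode, see [score_narrative()].
#' @return an object of class `ai_loco_result`: a list of fold entries,
#'   each with `held_out`, `protected`, `reports` (named list of
#'   [quadrant_report()] objects), `manifest` (the fold model's training
#'   manifest) and `eval_accuracy`.
#' @export
leave_one_dataset_out <- function(annotations, config = train_config(),
                                  protected = character(),
                                  balance_seed = config$seed,
                                  max_details = 8L, by_task = TRUE,
                                  protected_model = c("all", "fold"),
                                  mode = "class") {
  stopifnot(inherits(annotations, "ai_annotations"))
  protected_model <- match.arg(protected_model)
  all_ds <- unique(annotations$narratives$dataset_id)
  unknown <- setdiff(protected, all_ds)
  if (length(unknown) > 0L) {
    stopf("protected dataset(s) not in corpus: %s",
          paste(unknown, collapse = ", "))
  }
  open_ds <- setdiff(all_ds, protected)
  if (length(open_ds) == 0L) {
    stopf("protected set covers every dataset; nothing to train on")
  }
  if (length(open_ds) < 2L) {
    stopf("leave-one-dataset-out requires >= 2 non-protected datasets")
  }

  folds <- list()
  fold_models <- list()
  for (held in open_ds) {
    train_ann <- filter_datasets(annotations, setdiff(open_ds, held))
    balanced <- .prepare_training(train_ann, balance_seed, max_details)
    model <- train_classifier(balanced, config)
    prep <- .prepare_eval(filter_datasets(annotations, held), max_details)
    scores <- .score_eval(prep, model, mode)
    folds[[length(folds) + 1L]] <- list(
      held_out = held,
      protected = FALSE,
      reports = .report_subgroups(scores, prep$truth, by_task),
      manifest = model$manifest,
      eval_accuracy = model$eval_accuracy
    )
    fold_models[[held]] <- model
  }

  if (length(protected) > 0L) {
    if (protected_model == "all") {
      balanced <- .prepare_training(filter_datasets(annotations, open_ds),
                                    balance_seed, max_details)
      full_model <- train_classifier(balanced, config)
      for (held in protected) {
        prep <- .prepare_eval(filter_datasets(annotations, held),
                              max_details)
        scores <- .score_eval(prep, full_model, mode)
        folds[[length(folds) + 1L]] <- list(
          held_out = held,
          protected = TRUE,
          protected_model = "all",
          reports = .report_subgroups(scores, prep$truth, by_task),
          manifest = full_model$manifest,
          eval_accuracy = full_model$eval_accuracy
        )
      }
    } else {
      for (held in protected) {
        prep <- .prepare_eval(filter_datasets(annotations, held),
                              max_details)
        for (fold_ds in names(fold_models)) {
          model <- fold_models[[fold_ds]]
          scores <- .score_eval(prep, model, mode)
          folds[[length(folds) + 1L]] <- list(
            held_out = held,
            protected = TRUE,
            protected_model = paste0("fold:", fold_ds),
            reports = .report_subgroups(scores, prep$truth, by_task),
            manifest = model$manifest,
            eval_accuracy = model$eval_accuracy
          )
        }
      }
    }
  }
  structure(folds, class = "ai_loco_result")
}

#' @export
print.ai_loco_result <- function(x, ...) {
  cat(sprintf("<ai_loco_result> %d evaluation(s)\n", length(x)))
  for (fold in x) {
    for (nm in names(fold$reports)) {
      rep <- fold$reports[[nm]]
      cat(sprintf(
        "  %s%s [%s]: r_int_int=%.3f r_ext_ext=%.3f r_int_ext=%.3f r_ext_int=%.3f (n=%d)\n",
        fold$held_out, ifelse(fold$protected, " (protected)", ""), nm,
        quadrant_r(rep, "int_int"), quadrant_r(rep, "ext_ext"),
        quadrant_r(rep, "int_ext"), quadrant_r(rep, "ext_int"),
        rep$n[1]
      ))
    }
  }
  invisible(x)
}

#' Serialize evaluation results to JSON
#'
#' One record per (fold, subgroup) with the four correlations, R-squared
#' values, p-values and n.
#'
#' @param result an `ai_loco_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_loco_report <- function(result, path) {
  stopifnot(inherits(result, "ai_loco_result"))
  records <- list()
  for (fold in result) {
    for (nm in names(fold$reports)) {
      rep <- fold$reports[[nm]]
      rec <- list(
        held_out = fold$held_out,
        protected = fold$protected,
        subgroup = nm,
        n = rep$n[1]
      )
      for (q in rep$quadrant) {
        rec[[paste0("r_", q)]] <- rep$r[rep$quadrant == q]
        rec[[paste0("p_", q)]] <- rep$p[rep$quadrant == q]
        rec[[paste0("r2_", q)]] <- rep$r_squared[rep$quadrant == q]
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
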