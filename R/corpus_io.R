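#' Read narratives from a spreadsheet
#'
#' The scoring entry point for users is "a spreadsheet with narratives": one
#' row per narrative with columns `narrative_id` and `text`, plus optional
#' `dataset_id` (the grouping key for leave-one-dataset-out work) and `task`
#' (a metadata tag such as memory / future / writing). Missing `dataset_id`
#' defaults to the file stem. Text is whitespace-normalized on read; rows
#' whose text is empty after normalization are dropped with a warning.
#'
#' @param path path to a `.csv` or `.xlsx` file.
#' @param format `"csv"` or `"xlsx"`; inferred from the extension by default.
#' @return a tibble with columns `narrative_id`, `dataset_id`, `task`,
#'   `text`, one row per narrative in file order.
#' @export
read_narratives <- function(path, format = c("auto", "csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv",
      xlsx = "xlsx",
      stopf("cannot infer format from extension '%s'; pass format=", ext)
    )
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readxl::read_xlsx(path)
  }
  for (col in c("narrative_id", "text")) {
    if (!col %in% names(raw)) {
      stopf("narrative file %s lacks required column '%s'", path, col)
    }
  }
  stem <- tools::file_path_sans_ext(basename(path))
  out <- tibble::tibble(
    narrative_id = as.character(raw$narrative_id),
    dataset_id = if ("dataset_id" %in% names(raw)) {
      as.character(raw$dataset_id)
    } else {
      stem
    },
    task = if ("task" %in% names(raw)) as.character(raw$task) else "other",
    text = normalize_whitespace(as.character(raw$text))
  )
  dup <- unique(out$narrative_id[duplicated(out$narrative_id)])
  if (length(dup) > 0L) {
    stopf("duplicate narrative_id(s): %s", paste(dup, collapse = ", "))
  }
  empty <- !nzchar(out$text) | is.na(out$text)
  if (any(empty)) {
    warnf("dropping %d narrative(s) with empty text: %s", sum(empty),
          paste(out$narrative_id[empty], collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  out
}

#' Write narratives to CSV
#'
#' @param narratives narrative tibble (see [read_narratives()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_narratives <- function(narratives, path) {
  readr::write_csv(narratives, path)
  invisible(path)
}

#' Construct an annotated corpus
#'
#' The ground-truth container for training and validation: narratives plus
#' their ordered internal/external span annotations with manual detail
#' counts. Segment word counts and per-narrative totals (internal/external
#' details and words) are always recomputed from the segments; totals
#' supplied by the caller are checked against the recomputed values and a
#' mismatch is an error naming the narrative.
#'
#' @param narratives narrative tibble with `narrative_id`, `dataset_id`,
#'   `task`, `text`.
#' @param segments tibble with `narrative_id`, `segment_index`, `text`,
#'   `category` (`"internal"` or `"external"`), `detail_count`.
#' @param totals optional tibble of provided per-narrative totals
#'   (`narrative_id`, `internal_details`, `external_details`,
#'   `internal_words`, `external_words`) to check against.
#' @return an object of class `ai_annotations`: a list with elements
#'   `narratives` and `segments`.
#' @export
annotated_corpus <- function(narratives, segments, totals = NULL) {
  stopifnot(is.data.frame(narratives), is.data.frame(segments))
  need_n <- c("narrative_id", "text")
  need_s <- c("narrative_id", "segment_index", "text", "category",
              "detail_count")
  for (col in need_n) {
    if (!col %in% names(narratives)) stopf("narratives lack column '%s'", col)
  }
  for (col in need_s) {
    if (!col %in% names(segments)) stopf("segments lack column '%s'", col)
  }
  narratives <- tibble::as_tibble(narratives)
  if (!"dataset_id" %in% names(narratives)) narratives$dataset_id <- "corpus"
  if (!"task" %in% names(narratives)) narratives$task <- "other"
  narratives$text <- normalize_whitespace(narratives$text)

  segments <- tibble::as_tibble(segments)
  bad <- setdiff(unique(segments$category), c("internal", "external"))
  if (length(bad) > 0L) {
    stopf("invalid segment category value(s): %s", paste(bad, collapse = ", "))
  }
  if (any(segments$detail_count < 0 | segments$detail_count %% 1 != 0)) {
    stopf("detail_count must be a non-negative integer")
  }
  segments$detail_count <- as.integer(segments$detail_count)
  segments$text <- normalize_whitespace(segments$text)
  segments <- segments[order(match(segments$narrative_id,
                                   narratives$narrative_id),
                             segments$segment_index), , drop = FALSE]
  segments$word_count <- word_count(segments$text)

  orphan <- setdiff(unique(segments$narrative_id), narratives$narrative_id)
  if (length(orphan) > 0L) {
    stopf("segments reference unknown narrative_id(s): %s",
          paste(orphan, collapse = ", "))
  }

  # spans concatenated in order must reconstruct the narrative text
  rebuilt <- vapply(
    narratives$narrative_id,
    function(id) {
      paste(segments$text[segments$narrative_id == id], collapse = " ")
    },
    character(1), USE.NAMES = FALSE
  )
  mismatch <- normalize_whitespace(rebuilt) != narratives$text
  if (any(mismatch)) {
    stopf("segments do not reconstruct narrative text for: %s",
          paste(narratives$narrative_id[mismatch], collapse = ", "))
  }

  obj <- structure(
    list(narratives = narratives, segments = segments),
    class = "ai_annotations"
  )
  if (!is.null(totals)) {
    got <- annotation_totals(obj)
    m <- merge(totals, got, by = "narrative_id",
               suffixes = c(".given", ".computed"))
    for (col in c("internal_details", "external_details",
                  "internal_words", "external_words")) {
      gcol <- paste0(col, ".given")
      ccol <- paste0(col, ".computed")
      if (gcol %in% names(m)) {
        off <- m[[gcol]] != m[[ccol]]
        if (any(off)) {
          stopf("provided %s disagrees with recomputed value for: %s",
                col, paste(m$narrative_id[off], collapse = ", "))
        }
      }
    }
  }
  obj
}

#' @export
print.ai_annotations <- function(x, ...) {
  cat(sprintf(
    "<ai_annotations> %d narratives, %d segments, %d dataset(s)\n",
    nrow(x$narratives), nrow(x$segments),
    length(unique(x$narratives$dataset_id))
  ))
  invisible(x)
}

#' Per-narrative annotation totals
#'
#' Recomputes, for every narrative, the manual internal/external detail
#' counts and the internal/external word counts from its segments. These
#' word counts are the quantities the automated scorer estimates.
#'
#' @param annotations an `ai_annotations` object.
#' @return tibble with one row per narrative: `narrative_id`, `dataset_id`,
#'   `task`, `internal_details`, `external_details`, `internal_words`,
#'   `external_words`, `total_words`.
#' @export
annotation_totals <- function(annotations) {
  stopifnot(inherits(annotations, "ai_annotations"))
  seg <- annotations$segments
  agg <- seg |>
    dplyr::group_by(.data$narrative_id) |>
    dplyr::summarise(
      internal_details = sum(.data$detail_count[.data$category == "internal"]),
      external_details = sum(.data$detail_count[.data$category == "external"]),
      internal_words = sum(.data$word_count[.data$category == "internal"]),
      external_words = sum(.data$word_count[.data$category == "external"]),
      .groups = "drop"
    )
  out <- dplyr::left_join(
    annotations$narratives[, c("narrative_id", "dataset_id", "task")],
    agg, by = "narrative_id"
  )
  num <- c("internal_details", "external_details",
           "internal_words", "external_words")
  for (col in num) out[[col]][is.na(out[[col]])] <- 0L
  out$total_words <- out$internal_words + out$external_words
  out
}

#' Subset an annotated corpus by dataset
#'
#' @param annotations an `ai_annotations` object.
#' @param dataset_ids datasets to keep.
#' @return an `ai_annotations` object restricted to those datasets.
#' @export
filter_datasets <- function(annotations, dataset_ids) {
  stopifnot(inherits(annotations, "ai_annotations"))
  keep <- annotations$narratives$dataset_id %in% dataset_ids
  ids <- annotations$narratives$narrative_id[keep]
  annotated_corpus(
    annotations$narratives[keep, , drop = FALSE],
    annotations$segments[annotations$segments$narrative_id %in% ids, ,
                         drop = FALSE]
  )
}

#' Read annotations from segment-level CSV
#'
#' The interchange format for annotated corpora is a segment-level CSV (one
#' row per span, in order), optionally paired with a narrative-level CSV
#' carrying `dataset_id`/`task` metadata and totals to verify. If no
#' narrative file is given, narrative text is rebuilt by concatenating each
#' narrative's segments and `dataset_id` defaults to the segment file stem.
#'
#' @param segments_path CSV with columns `narrative_id`, `segment_index`,
#'   `text`, `category`, `detail_count`.
#' @param narratives_path optional CSV with columns `narrative_id`, `text`,
#'   and optionally `dataset_id`, `task`, and total columns
#'   (`internal_details`, ...) to check.
#' @return an `ai_annotations` object.
#' @export
read_annotations <- function(segments_path, narratives_path = NULL) {
  seg <- readr::read_csv(segments_path, show_col_types = FALSE,
                         progress = FALSE)
  need <- c("narrative_id", "segment_index", "text", "category",
            "detail_count")
  missing <- setdiff(need, names(seg))
  if (length(missing) > 0L) {
    stopf("annotation file %s lacks column(s): %s", segments_path,
          paste(missing, collapse = ", "))
  }
  seg$narrative_id <- as.character(seg$narrative_id)
  totals <- NULL
  if (!is.null(narratives_path)) {
    nar <- readr::read_csv(narratives_path, show_col_types = FALSE,
                           progress = FALSE)
    nar$narrative_id <- as.character(nar$narrative_id)
    tot_cols <- intersect(
      c("internal_details", "external_details",
        "internal_words", "external_words"),
      names(nar)
    )
    if (length(tot_cols) > 0L) {
      totals <- nar[, c("narrative_id", tot_cols)]
    }
    if (!"text" %in% names(nar)) {
      nar$text <- .rebuild_text(seg, nar$narrative_id)
    }
    narratives <- nar[, intersect(
      c("narrative_id", "dataset_id", "task", "text"), names(nar)
    )]
  } else {
    ids <- unique(seg$narrative_id)
    narratives <- tibble::tibble(
      narrative_id = ids,
      dataset_id = if ("dataset_id" %in% names(seg)) {
        vapply(ids, function(i) {
          as.character(seg$dataset_id[seg$narrative_id == i][1])
        }, character(1), USE.NAMES = FALSE)
      } else {
        tools::file_path_sans_ext(basename(segments_path))
      },
      task = if ("task" %in% names(seg)) {
        vapply(ids, function(i) {
          as.character(seg$task[seg$narrative_id == i][1])
        }, character(1), USE.NAMES = FALSE)
      } else {
        "other"
      },
      text = .rebuild_text(seg, ids)
    )
  }
  annotated_corpus(narratives, seg[, need], totals = totals)
}

.rebuild_text <- function(seg, ids) {
  vapply(ids, function(id) {
    rows <- seg[seg$narrative_id == id, , drop = FALSE]
    rows <- rows[order(rows$segment_index), , drop = FALSE]
    normalize_whitespace(paste(rows$text, collapse = " "))
  }, character(1), USE.NAMES = FALSE)
}

#' Write annotations to segment-level CSV
#'
#' @param annotations an `ai_annotations` object.
#' @param segments_path output CSV for segments.
#' @param narratives_path optional output CSV for narrative metadata and
#'   totals (enables full-fidelity round-trips of `dataset_id`/`task`).
#' @return `segments_path`, invisibly.
#' @export
write_annotations <- function(annotations, segments_path,
                              narratives_path = NULL) {
  stopifnot(inherits(annotations, "ai_annotations"))
  seg <- annotations$segments[, c("narrative_id", "segment_index", "text",
                                  "category", "detail_count")]
  readr::write_csv(seg, segments_path)
  if (!is.null(narratives_path)) {
    tot <- annotation_totals(annotations)
    nar <- dplyr::left_join(annotations$narratives, tot,
                            by = c("narrative_id", "dataset_id", "task"))
    readr::write_csv(nar, narratives_path)
  }
  invisible(segments_path)
}

#' Write narrative scores to CSV
#'
#' @param scores tibble with columns `narrative_id`,
#'   `predicted_internal_words`, `predicted_external_words`, `total_words`
#'   (see [score_corpus()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  need <- c("narrative_id", "predicted_internal_words",
            "predicted_external_words", "total_words")
  missing <- setdiff(need, names(scores))
  if (length(missing) > 0L) {
    stopf("scores lack column(s): %s", paste(missing, collapse = ", "))
  }
  readr::write_csv(scores[, intersect(c(need, "empty"), names(scores))], path)
  invisible(path)
}

#' Read narrative scores from CSV
#'
#' @param path CSV written by [write_scores()].
#' @return score tibble, rows in file order.
#' @export
read_scores <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$narrative_id <- as.character(out$narrative_id)
  tibble::as_tibble(out)
}
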