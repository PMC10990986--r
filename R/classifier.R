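#' Training configuration for the sentence classifier
#'
#' The fine-tuning recipe: three epochs, batch size 16 during training and
#' 64 for evaluation, 500 warmup steps, 0.01 weight decay, accuracy as the
#' evaluation criterion. Batch/epoch/warmup fields parameterize
#' gradient-based backends; the lightweight backend consumes `weight_decay`
#' (as its L2 penalty) and `seed`, and records the rest in its manifest so
#' the full configuration is always explicit.
#'
#' @param epochs training epochs (default 3).
#' @param train_batch_size per-device training batch size (default 16).
#' @param eval_batch_size evaluation batch size (default 64).
#' @param warmup_steps learning-rate warmup steps (default 500).
#' @param weight_decay L2 regularization strength (default 0.01).
#' @param backbone backend identifier; `"lightweight"` is the built-in
#'   token-count + multinomial linear model backend.
#' @param seed integer seed for every stochastic step (holdout split,
#'   any backend sampling).
#' @param holdout_fraction fraction of the training pool held out
#'   (stratified by class) to log accuracy (default 0.1).
#' @return a list of class `ai_train_config`.
#' @export
train_config <- function(epochs = 3L,
                         train_batch_size = 16L,
                         eval_batch_size = 64L,
                         warmup_steps = 500L,
                         weight_decay = 0.01,
                         backbone = "lightweight",
                         seed = 1L,
                         holdout_fraction = 0.1) {
  counts <- c(epochs = epochs, train_batch_size = train_batch_size,
              eval_batch_size = eval_batch_size)
  if (any(counts < 1)) stopf("epochs and batch sizes must be positive")
  if (warmup_steps < 0) stopf("warmup_steps must be >= 0")
  if (weight_decay < 0) stopf("weight_decay must be >= 0")
  if (holdout_fraction < 0 || holdout_fraction >= 1) {
    stopf("holdout_fraction must lie in [0, 1)")
  }
  structure(
    list(
      epochs = as.integer(epochs),
      train_batch_size = as.integer(train_batch_size),
      eval_batch_size = as.integer(eval_batch_size),
      warmup_steps = as.integer(warmup_steps),
      weight_decay = weight_decay,
      backbone = backbone,
      seed = as.integer(seed),
      eval_metric = "accuracy",
      holdout_fraction = holdout_fraction
    ),
    class = "ai_train_config"
  )
}

.tokenize <- function(text) {
  toks <- strsplit(gsub("[^[:alnum:]']+", " ", tolower(text)), " ",
                   fixed = TRUE)
  lapply(toks, function(t) t[nzchar(t)])
}

# sparse document-term count matrix over a fixed vocabulary
.count_matrix <- function(text, vocab) {
  toks <- .tokenize(text)
  ij <- lapply(seq_along(toks), function(i) {
    idx <- match(toks[[i]], vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(NULL)
    tab <- table(idx)
    cbind(i = i, j = as.integer(names(tab)), x = as.integer(tab))
  })
  ijm <- do.call(rbind, ij)
  if (is.null(ijm)) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(text), length(vocab))))
  }
  Matrix::sparseMatrix(i = ijm[, "i"], j = ijm[, "j"], x = ijm[, "x"],
                       dims = c(length(text), length(vocab)))
}

#' Train a four-class sentence classifier
#'
#' Fits a classifier of the internal-content proportion class of a sentence
#' behind a backend-agnostic interface. The built-in `"lightweight"`
#' backbone uses token-count features and a multinomial linear model with an
#' L2 penalty (`weight_decay`), fit by [glmnet::glmnet()]; it is fully
#' deterministic given the config seed and runs on a single CPU. Other
#' backbones (e.g. a fine-tuned transformer encoder with a linear
#' classification head) plug in through the same interface by registering a
#' recognized backbone id; an unknown id is a configuration error.
#'
#' A stratified holdout (10% by default) is split off before fitting and
#' the model's accuracy on it is logged in the returned object.
#'
#' @param labeled tibble with columns `text` and `cls` — normally the
#'   balanced output of [balance_classes()]. An unbalanced input trains
#'   with a warning (deliberate ablations are allowed).
#' @param config an [train_config()] object.
#' @return an object of class `ai_classifier` with fields `backend`,
#'   `vocab`, `beta` (coefficient matrix, `(Intercept)` row first),
#'   `levels`, `fitted_levels`, `config`, `eval_accuracy`, and a `manifest`
#'   recording the training narrative ids.
#' @export
train_classifier <- function(labeled, config = train_config()) {
  stopifnot(inherits(config, "ai_train_config"))
  for (col in c("text", "cls")) {
    if (!col %in% names(labeled)) stopf("`labeled` lacks column '%s'", col)
  }
  if (config$backbone != "lightweight") {
    stopf("unknown backbone '%s'; available: lightweight", config$backbone)
  }
  y <- factor(as.character(labeled$cls), levels = class_levels())
  present <- levels(droplevels(y))
  if (length(present) < 2L) {
    stopf("training data contain %d class(es); at least 2 required",
          length(present))
  }
  counts <- table(droplevels(y))
  if (length(unique(counts)) > 1L) {
    warnf("training classes are not balanced (counts: %s)",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }

  # stratified holdout for logged evaluation accuracy
  hold <- integer()
  if (config$holdout_fraction > 0) {
    hold <- with_seed(config$seed, {
      unlist(lapply(present, function(lv) {
        pool <- which(y == lv)
        n_hold <- floor(length(pool) * config$holdout_fraction)
        if (n_hold == 0L) return(integer())
        pool[sample.int(length(pool), n_hold)]
      }))
    })
  }
  fit_idx <- setdiff(seq_len(nrow(labeled)), hold)
  y_fit <- droplevels(y[fit_idx])
  if (length(levels(y_fit)) < 2L) {
    fit_idx <- seq_len(nrow(labeled))
    hold <- integer()
    y_fit <- droplevels(y)
  }

  vocab <- sort(unique(unlist(.tokenize(labeled$text[fit_idx]))))
  x_fit <- .count_matrix(labeled$text[fit_idx], vocab)
  lambda <- max(config$weight_decay, 1e-6)
  fit <- glmnet::glmnet(
    x_fit, y_fit, family = "multinomial", alpha = 0,
    lambda = lambda, standardize = FALSE
  )
  co <- glmnet::coef.glmnet(fit, s = lambda)
  beta <- do.call(cbind, lapply(co, function(m) as.numeric(m[, 1])))
  rownames(beta) <- c("(Intercept)", vocab)
  colnames(beta) <- levels(y_fit)

  model <- structure(
    list(
      backend = "lightweight",
      vocab = vocab,
      beta = beta,
      levels = class_levels(),
      fitted_levels = levels(y_fit),
      config = config,
      eval_accuracy = NA_real_,
      manifest = list(
        backend = "lightweight",
        n_train = length(fit_idx),
        n_holdout = length(hold),
        trained_narrative_ids =
          if ("narrative_id" %in% names(labeled)) {
            sort(unique(as.character(labeled$narrative_id)))
          } else {
            character()
          }
      )
    ),
    class = "ai_classifier"
  )
  if (length(hold) > 0L) {
    pred <- predict_class(model, labeled[hold, , drop = FALSE])
    model$eval_accuracy <- mean(as.character(pred$cls) ==
                                as.character(y[hold]))
    model$manifest$eval_accuracy <- model$eval_accuracy
  }
  model
}

#' @export
print.ai_classifier <- function(x, ...) {
  cat(sprintf(
    "<ai_classifier> backend=%s, %d features, holdout accuracy=%s\n",
    x$backend, length(x$vocab),
    ifelse(is.na(x$eval_accuracy), "n/a", sprintf("%.3f", x$eval_accuracy))
  ))
  invisible(x)
}

#' Predict proportion classes for sentences
#'
#' Returns the argmax class and the full class-probability vector (summing
#' to 1) for each sentence. Probability ties are broken toward the higher
#' (more internal) class. Empty sentences are an error: they must be
#' filtered before prediction.
#'
#' @param model an `ai_classifier` (trained or oracle).
#' @param sentences tibble with a `text` column; the oracle backend
#'   additionally requires `narrative_id` and `index`.
#' @return tibble with `cls` (ordered factor) and one probability column
#'   per class (`p_P0` ... `p_P100`).
#' @export
predict_class <- function(model, sentences) {
  stopifnot(inherits(model, "ai_classifier"))
  if (is.character(sentences)) {
    sentences <- tibble::tibble(text = sentences)
  }
  if (!"text" %in% names(sentences)) stopf("`sentences` lacks column 'text'")
  if (nrow(sentences) == 0L) {
    out <- tibble::tibble(cls = bin_fraction(numeric()))
    for (lv in class_levels()) out[[paste0("p_", lv)]] <- numeric()
    return(out)
  }
  if (any(word_count(sentences$text) == 0L)) {
    stopf("cannot predict on empty sentences; filter them upstream")
  }
  if (model$backend == "oracle") {
    return(.predict_oracle(model, sentences))
  }
  x <- .count_matrix(sentences$text, model$vocab)
  eta <- as.matrix(cbind(1, x) %*% model$beta)
  eta <- eta - apply(eta, 1, max)
  p_fit <- exp(eta)
  p_fit <- p_fit / rowSums(p_fit)
  probs <- matrix(0, nrow(p_fit), length(model$levels),
                  dimnames = list(NULL, model$levels))
  probs[, colnames(p_fit)] <- p_fit
  .classify_probs(probs, model$levels)
}

# argmax with ties toward the higher class; probabilities renormalized to
# sum exactly to 1
.classify_probs <- function(probs, levels) {
  probs <- probs / rowSums(probs)
  pick <- apply(probs, 1, function(p) max(which(p >= max(p) - 1e-12)))
  out <- tibble::tibble(
    cls = factor(levels[pick], levels = levels, ordered = TRUE)
  )
  for (i in seq_along(levels)) {
    out[[paste0("p_", levels[i])]] <- probs[, i]
  }
  out
}

#' Oracle classifier from ground-truth annotations
#'
#' A reference "model" that returns the true proportion class of each
#' sentence (the binned true internal fraction), looked up by
#' `narrative_id` and sentence `index`. Used for oracle-equivalence and
#' conservation checks of the scoring pipeline: it isolates the
#' aggregation arithmetic from classifier error.
#'
#' @param annotations an `ai_annotations` object.
#' @return an `ai_classifier` with backend `"oracle"`.
#' @export
oracle_classifier <- function(annotations) {
  tab <- sentence_annotations(annotations)
  tab <- label_sentences(tab[tab$word_count > 0L, , drop = FALSE])
  structure(
    list(
      backend = "oracle",
      lookup = tab[, c("narrative_id", "index", "cls")],
      levels = class_levels(),
      manifest = list(backend = "oracle")
    ),
    class = "ai_classifier"
  )
}

.predict_oracle <- function(model, sentences) {
  for (col in c("narrative_id", "index")) {
    if (!col %in% names(sentences)) {
      stopf("oracle backend requires column '%s'", col)
    }
  }
  key <- paste(sentences$narrative_id, sentences$index)
  lk <- paste(model$lookup$narrative_id, model$lookup$index)
  idx <- match(key, lk)
  if (anyNA(idx)) {
    stopf("oracle has no label for sentence(s): %s",
          paste(utils::head(key[is.na(idx)], 5L), collapse = "; "))
  }
  cls <- model$lookup$cls[idx]
  probs <- matrix(0, length(idx), length(model$levels),
                  dimnames = list(NULL, model$levels))
  probs[cbind(seq_along(idx), match(as.character(cls), model$levels))] <- 1
  .classify_probs(probs, model$levels)
}

#' Save a trained classifier to a directory
#'
#' Writes a plain-text artifact set: `manifest.json` (backend, config,
#' label map, evaluation accuracy, training narrative ids), `vocab.txt`,
#' and `coef.csv` (one row per feature, one column per fitted class).
#'
#' @param model a lightweight-backend `ai_classifier`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_classifier <- function(model, dir) {
  stopifnot(inherits(model, "ai_classifier"))
  if (model$backend != "lightweight") {
    stopf("only the lightweight backend supports serialization")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format_version = 1L,
    backend = model$backend,
    levels = model$levels,
    fitted_levels = model$fitted_levels,
    eval_accuracy = model$eval_accuracy,
    config = unclass(model$config),
    manifest = model$manifest
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(model$vocab, file.path(dir, "vocab.txt"))
  coefs <- tibble::as_tibble(model$beta, rownames = "feature")
  readr::write_csv(coefs, file.path(dir, "coef.csv"))
  invisible(dir)
}

#' Load a classifier saved by [save_classifier()]
#'
#' @param dir directory containing `manifest.json`, `vocab.txt`, `coef.csv`.
#' @return an `ai_classifier`.
#' @export
load_classifier <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  vocab <- readLines(file.path(dir, "vocab.txt"))
  coefs <- readr::read_csv(file.path(dir, "coef.csv"),
                           show_col_types = FALSE, progress = FALSE)
  beta <- as.matrix(coefs[, -1, drop = FALSE])
  rownames(beta) <- coefs$feature
  cfg <- manifest$config
  config <- train_config(
    epochs = cfg$epochs, train_batch_size = cfg$train_batch_size,
    eval_batch_size = cfg$eval_batch_size, warmup_steps = cfg$warmup_steps,
    weight_decay = cfg$weight_decay, backbone = cfg$backbone,
    seed = cfg$seed, holdout_fraction = cfg$holdout_fraction
  )
  structure(
    list(
      backend = manifest$backend,
      vocab = vocab,
      beta = beta,
      levels = manifest$levels,
      fitted_levels = manifest$fitted_levels,
      config = config,
      eval_accuracy = manifest$eval_accuracy,
      manifest = manifest$manifest
    ),
    class = "ai_classifier"
  )
}
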