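#' Fit one of the implemented models by name
#'
#' Convenience dispatcher used by the benchmark driver and the CLI.
#'
#' @param model_name One of `"ptic"`, `"logit_ptic"`, `"naive_bayes"`.
#' @param corpus Labeled [tokenized_corpus()].
#' @param min_count Vocabulary threshold.
#' @param positive Positive-class name.
#' @param vocab Optional explicit vocabulary.
#' @param config [train_config()] for logit PTIC (ignored otherwise).
#' @param ... Extra arguments passed to the underlying fit function.
#' @return A fitted model object.
#' @export
fit_model <- function(model_name = c("ptic", "logit_ptic", "naive_bayes"),
                      corpus, min_count = 5, positive = NULL,
                      vocab = NULL, config = train_config(), ...) {
  model_name <- match.arg(model_name)
  switch(model_name,
    ptic = ptic_fit(corpus, positive = positive, min_count = min_count,
                    vocab = vocab, ...),
    logit_ptic = {
      base <- ptic_fit(corpus, positive = positive,
                       min_count = min_count, vocab = vocab, ...)
      train_logit_ptic(logit_ptic(base), corpus, config)
    },
    naive_bayes = fit_nb(corpus, min_count = min_count,
                         positive = positive, vocab = vocab, ...)
  )
}

# continuous decision score for ROC/threshold analysis: PTIC and NB use
# the class-score margin, logit PTIC the positive-class probability
decision_scores <- function(model, corpus) {
  if (inherits(model, "logit_ptic")) {
    as.numeric(forward(model, corpus))
  } else {
    classify(model, corpus)$margin
  }
}

#' Compare models across evaluation corpora
#'
#' Fits each requested model once on the training corpus and evaluates it
#' on every evaluation corpus, producing one metrics row per
#' (model, corpus) cell. Deterministic given `seed`. The returned table
#' carries a `manifest` attribute (configuration and seed) sufficient to
#' reproduce it.
#'
#' @param train_corpus Labeled corpus data frame.
#' @param eval_corpora Named list of labeled corpus data frames.
#' @param models Character vector of model names (see [fit_model()]).
#' @param min_count Vocabulary threshold.
#' @param threshold Positive-decision threshold for logit PTIC.
#' @param config [train_config()] for logit PTIC; its seed is reset to
#'   `seed`.
#' @param seed Run seed recorded in the manifest.
#' @return Data frame with columns `model`, `corpus`, and the metrics of
#'   [classification_metrics()].
#' @export
run_compare <- function(train_corpus, eval_corpora,
                        models = c("ptic", "logit_ptic", "naive_bayes"),
                        min_count = 5, threshold = 0.5,
                        config = train_config(), seed = 1) {
  stopifnot(is.list(eval_corpora), length(eval_corpora) >= 1)
  if (is.null(names(eval_corpora))) {
    names(eval_corpora) <- sprintf("eval%d", seq_along(eval_corpora))
  }
  for (nm in names(eval_corpora)) {
    if (!"label" %in% names(eval_corpora[[nm]])) {
      stop("evaluation corpus '", nm, "' has no labels")
    }
  }
  config$seed <- as.integer(seed)
  tc_train <- tokenize_corpus(train_corpus)
  tc_evals <- lapply(eval_corpora, tokenize_corpus)
  rows <- list()
  for (mn in models) {
    fitted <- fit_model(mn, tc_train, min_count = min_count,
                        config = config)
    for (nm in names(tc_evals)) {
      pred <- if (inherits(fitted, "logit_ptic")) {
        classify(fitted, tc_evals[[nm]], threshold = threshold)
      } else {
        classify(fitted, tc_evals[[nm]])
      }
      met <- classification_metrics(pred$predicted,
                                    tc_evals[[nm]]$label,
                                    positive = positive_of(fitted))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(model = mn, corpus = nm,
                         stringsAsFactors = FALSE),
              as.data.frame(met))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- list(models = models, min_count = min_count,
                                threshold = threshold, seed = seed,
                                config = unclass(config),
                                package = as.character(
                                  utils::packageVersion("pticlass")))
  out
}

positive_of <- function(model) {
  if (inherits(model, "logit_ptic")) model$base$positive else model$positive
}

#' Sweep one experimental axis
#'
#' Refits and re-evaluates a model along one of four axes: `min_count`
#' (vocabulary threshold), `dict_size` (top-k dictionary truncation, see
#' [shrink_vocabulary()]), `negative_multiplier` (evaluation-set
#' imbalance via [rebalance()]), or `noise_fraction` (training label
#' noise via [inject_label_noise()]). Invalid axis values produce a
#' flagged error row; the sweep continues, and the output has exactly one
#' row per requested value.
#'
#' @param axis One of `"min_count"`, `"dict_size"`,
#'   `"negative_multiplier"`, `"noise_fraction"`.
#' @param values Non-empty sorted vector of axis values.
#' @param model Model name (see [fit_model()]).
#' @param train_corpus,eval_corpus Labeled corpus data frames.
#' @param min_count Baseline vocabulary threshold (for axes other than
#'   `min_count`).
#' @param rank_by Dictionary ranking rule for the `dict_size` axis:
#'   `"frequency"` (default) or `"npmi"`.
#' @param threshold Positive-decision threshold for logit PTIC.
#' @param config [train_config()] for logit PTIC.
#' @param seed Run seed.
#' @return Data frame with one row per value: `axis`, `value`,
#'   `vocab_size`, the metrics columns, and `error` (`NA` for clean rows,
#'   the error message otherwise).
#' @export
run_sweep <- function(axis = c("min_count", "dict_size",
                               "negative_multiplier", "noise_fraction"),
                      values, model = "ptic", train_corpus, eval_corpus,
                      min_count = 5, rank_by = "frequency",
                      threshold = 0.5, config = train_config(), seed = 1) {
  axis <- match.arg(axis)
  if (length(values) == 0) stop("values must be non-empty")
  if (is.unsorted(values)) stop("values must be sorted")
  config$seed <- as.integer(seed)
  rows <- lapply(values, function(v) {
    res <- tryCatch(
      sweep_cell(axis, v, model, train_corpus, eval_corpus, min_count,
                 rank_by, threshold, config, seed),
      error = function(e) list(metrics = NULL, vocab_size = NA_integer_,
                               error = conditionMessage(e))
    )
    met <- if (is.null(res$metrics)) {
      data.frame(tp = NA, fp = NA, tn = NA, fn = NA, accuracy = NA,
                 precision = NA, recall = NA, f1 = NA)
    } else as.data.frame(res$metrics)
    cbind(data.frame(axis = axis, value = v,
                     vocab_size = res$vocab_size,
                     stringsAsFactors = FALSE),
          met,
          data.frame(error = if (is.null(res$error)) NA_character_
                             else res$error,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- list(axis = axis, values = values,
                                model = model, min_count = min_count,
                                rank_by = rank_by, threshold = threshold,
                                seed = seed, config = unclass(config))
  out
}

sweep_cell <- function(axis, v, model, train_corpus, eval_corpus,
                       min_count, rank_by, threshold, config, seed) {
  if (axis == "min_count" && (!is.finite(v) || v < 1)) {
    stop("min_count value must be >= 1")
  }
  if (axis == "dict_size" && (!is.finite(v) || v < 1)) {
    stop("dict_size value must be >= 1")
  }
  train <- train_corpus
  eval_c <- eval_corpus
  if (axis == "noise_fraction") {
    train <- inject_label_noise(train, v, seed = seed + 1L)
  }
  if (axis == "negative_multiplier") {
    eval_c <- rebalance(eval_c, v, seed = seed + 2L)
  }
  tc_train <- tokenize_corpus(train)
  tc_eval <- tokenize_corpus(eval_c)
  mc <- if (axis == "min_count") v else min_count
  vocab <- NULL
  if (axis == "dict_size") {
    # rank the full min_count vocabulary, then truncate to the top v
    base <- ptic_fit(tc_train, min_count = min_count)
    vocab <- shrink_vocabulary(base, v, by = rank_by)$vocab
  }
  fitted <- fit_model(model, tc_train, min_count = mc, vocab = vocab,
                      config = config)
  pred <- if (inherits(fitted, "logit_ptic")) {
    classify(fitted, tc_eval, threshold = threshold)
  } else {
    classify(fitted, tc_eval)
  }
  vocab_size <- length(if (inherits(fitted, "logit_ptic"))
    fitted$base$vocab else fitted$vocab)
  list(metrics = classification_metrics(pred$predicted, tc_eval$label,
                                        positive = positive_of(fitted)),
       vocab_size = vocab_size, error = NULL)
}

#' ROC and best-F1 threshold for a fitted model
#'
#' Computes the ROC curve of the model's continuous decision scores on a
#' labeled corpus and scans the distinct scores for the decision
#' threshold maximizing F1 -- the threshold-moving analysis for
#' imbalanced test sets.
#'
#' @param model A fitted model object.
#' @param corpus Labeled corpus data frame or [tokenized_corpus()].
#' @return List with `roc` (a [roc_curve()]), `auc`, `best_threshold`
#'   (score cutoff maximizing F1; predict positive at score >= cutoff),
#'   and `best_f1`.
#' @export
run_threshold_analysis <- function(model, corpus) {
  tc <- if (inherits(corpus, "tokenized_corpus")) corpus
        else tokenize_corpus(corpus)
  if (is.null(tc$label)) stop("threshold analysis requires labels")
  pos <- positive_of(model)
  scores <- decision_scores(model, tc)
  roc <- roc_curve(scores, tc$label, positive = pos)
  cand <- sort(unique(scores))
  f1s <- vapply(cand, function(th) {
    pred <- ifelse(scores >= th, pos, paste0("not_", pos))
    lab <- ifelse(tc$label == pos, pos, paste0("not_", pos))
    classification_metrics(pred, lab, positive = pos)$f1
  }, numeric(1))
  best <- which.max(f1s)
  list(roc = roc, auc = roc$auc, best_threshold = cand[best],
       best_f1 = f1s[best])
}
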