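#' Fit a multinomial Naive Bayes baseline
#'
#' Event model: multinomial over tokens with multiplicity. Class priors
#' are document fractions; class-conditional word probabilities use
#' additive (Laplace) smoothing,
#' `P(w | c) = (token count of w in class c + alpha) /
#' (total in-vocabulary tokens in class c + alpha * |vocab|)`,
#' so no conditional probability is ever zero.
#'
#' @param corpus Labeled [tokenized_corpus()] with two classes.
#' @param alpha Smoothing pseudocount (> 0, default 1).
#' @param min_count Minimum total occurrence count for vocabulary entry
#'   (default 5, matching the PTIC convention).
#' @param positive Name of the positive class (default `"pos"` when
#'   present).
#' @param vocab Optional explicit vocabulary.
#' @return An object of class `"nb_model"` with `log_prior`, `log_cond`
#'   (class x word matrix), `alpha` and `vocab`.
#' @export
fit_nb <- function(corpus, alpha = 1, min_count = 5, positive = NULL,
                   vocab = NULL) {
  stopifnot(inherits(corpus, "tokenized_corpus"), alpha > 0)
  classes <- sort(unique(corpus$label))
  if (length(classes) != 2) {
    stop("fit_nb() requires exactly two classes; got: ",
         paste(classes, collapse = ", "))
  }
  positive <- resolve_positive(positive, classes)
  negative <- setdiff(classes, positive)
  if (is.null(vocab)) {
    vocab <- build_vocabulary(corpus, min_count)
  } else {
    vocab <- intersect(sort(vocab),
                       unique(unlist(corpus$tokens, use.names = FALSE)))
  }
  if (length(vocab) == 0) stop("empty vocabulary")
  counts <- count_table(corpus, vocab)
  if (any(counts$N_class == 0)) stop("a class has zero documents")
  tok_cw <- counts$token_class_word
  log_cond <- log(tok_cw + alpha) -
    log(rowSums(tok_cw) + alpha * length(vocab))
  structure(
    list(
      class_labels = c(positive, negative),
      positive = positive,
      negative = negative,
      log_prior = setNames(log(counts$N_class[c(positive, negative)] /
                                 counts$N), c(positive, negative)),
      log_cond = log_cond[c(positive, negative), , drop = FALSE],
      alpha = alpha,
      min_count = min_count,
      vocab = vocab
    ),
    class = "nb_model"
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("Multinomial Naive Bayes: %d words, alpha = %g\n",
              length(x$vocab), x$alpha))
  invisible(x)
}

#' Unnormalized per-class log posteriors
#'
#' `score(c) = log P(c) + sum over document tokens (with multiplicity) of
#' log P(token | c)`; out-of-vocabulary tokens are skipped. For an empty
#' document the scores equal the log priors.
#'
#' @param model A fitted [fit_nb()] model.
#' @param corpus A [tokenized_corpus()].
#' @return Numeric matrix, one row per document, one column per class
#'   (positive first).
#' @export
nb_log_posterior <- function(model, corpus) {
  stopifnot(inherits(model, "nb_model"),
            inherits(corpus, "tokenized_corpus"))
  dtm <- dtm_from_tokens(corpus$tokens, model$vocab)
  S <- as.matrix(dtm %*% t(model$log_cond))
  S <- sweep(S, 2, model$log_prior, "+")
  dimnames(S) <- list(corpus$doc_id, model$class_labels)
  S
}

#' @rdname classify
#' @export
classify.nb_model <- function(model, corpus, ...) {
  S <- nb_log_posterior(model, corpus)
  margin <- S[, model$positive] - S[, model$negative]
  data.frame(
    doc_id = corpus$doc_id,
    score_pos = S[, model$positive],
    score_neg = S[, model$negative],
    margin = margin,
    predicted = ifelse(margin > 0, model$positive, model$negative),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @export
predict.nb_model <- function(object, newdata, ...) {
  classify.nb_model(object, newdata, ...)
}
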