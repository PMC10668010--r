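#' Pointwise mutual information of a (class, word) pair
#'
#' `pmi = log( P(class, word) / (P(class) * P(word)) )` with natural
#' logarithms. Probabilities are document-level by default: `P(word)` is the
#' fraction of documents containing the word, `P(class)` the fraction of
#' documents in the class, and `P(class, word)` the fraction of documents
#' that are in the class and contain the word. A token-level probability
#' space (probabilities over token draws rather than document presence) is
#' available via `probability = "token"` for comparison. A zero joint count
#' yields `-Inf`; [npmi()] maps that case to its analytic limit.
#'
#' @param counts A [count_table()].
#' @param class A class label present in `counts$classes`.
#' @param word A vocabulary word.
#' @param probability `"document"` (default) or `"token"`.
#' @return Numeric scalar (possibly `-Inf`).
#' @export
pmi <- function(counts, class, word,
                probability = c("document", "token")) {
  probability <- match.arg(probability)
  p <- joint_probs(counts, class, word, probability)
  if (p$joint == 0) return(-Inf)
  log(p$joint / (p$class * p$word))
}

#' Normalized pointwise mutual information, bounded in [-1, 1]
#'
#' `npmi = pmi / (-log P(class, word))`. The normalization bounds the score
#' in `[-1, 1]`: -1 means class and word never co-occur, 0 independence,
#' +1 perfect co-occurrence. When the joint count is zero the analytic
#' limit -1 is returned, keeping downstream scores finite.
#'
#' @inheritParams pmi
#' @return Numeric scalar in `[-1, 1]`.
#' @export
npmi <- function(counts, class, word,
                 probability = c("document", "token")) {
  probability <- match.arg(probability)
  p <- joint_probs(counts, class, word, probability)
  if (p$joint == 0) return(-1)
  log(p$joint / (p$class * p$word)) / (-log(p$joint))
}

#' Positive pointwise mutual information
#'
#' `ppmi = max(pmi, 0)`: the PMI clamped at zero from below, an
#' alternative to normalization for taming the `-Inf` tail.
#'
#' @inheritParams pmi
#' @return Numeric scalar >= 0.
#' @export
ppmi <- function(counts, class, word,
                 probability = c("document", "token")) {
  max(pmi(counts, class, word, probability), 0)
}

joint_probs <- function(counts, class, word, probability) {
  stopifnot(inherits(counts, "ptic_counts"))
  if (!word %in% counts$vocab) stop("word not in vocabulary: ", word)
  if (!class %in% counts$classes) stop("unknown class: ", class)
  if (probability == "document") {
    list(joint = counts$N_class_word[class, word] / counts$N,
         class = counts$N_class[[class]] / counts$N,
         word = counts$N_word[[word]] / counts$N)
  } else {
    tot <- sum(counts$tokens_per_class)
    list(joint = counts$token_class_word[class, word] / tot,
         class = counts$tokens_per_class[[class]] / tot,
         word = sum(counts$token_class_word[, word]) / tot)
  }
}

#' Term frequency-inverse document frequency of a word in a document
#'
#' `tf-idf = n_word * (1/n) * log(N / N_word)` where `n` is the document's
#' total token count (all tokens, in- or out-of-vocabulary), `n_word` the
#' number of occurrences of the word in the document, `N` the number of
#' documents and `N_word` the number of documents containing the word.
#'
#' @param doc Character vector of document tokens.
#' @param word A vocabulary word.
#' @param counts A [count_table()] supplying `N` and `N_word`.
#' @return Numeric scalar >= 0; 0 when the word is absent from the document.
#' @export
tf_idf <- function(doc, word, counts) {
  stopifnot(inherits(counts, "ptic_counts"))
  if (!word %in% counts$vocab) stop("word not in vocabulary: ", word)
  n <- length(doc)
  if (n < 1) stop("document must contain at least one token")
  sum(doc == word) * (1 / n) * log(counts$N / counts$N_word[[word]])
}

#' Fit the PMI/TF-IDF classifier (PTIC)
#'
#' Builds the restricted vocabulary, tabulates document/class/word counts,
#' and stores the per-(class, word) association table (normalized PMI by
#' default, positive PMI optionally) together with the idf table and class
#' priors, all frozen at fit time. Scoring a document then sums
#' `tf-idf(word) * association(class, word)` over its distinct
#' in-vocabulary words, and [classify()] takes the argmax.
#'
#' @param corpus Labeled [tokenized_corpus()] with exactly two classes and
#'   at least one document per class.
#' @param positive Name of the positive class. Defaults to `"pos"` when
#'   that tag is present; otherwise it must be given explicitly.
#' @param min_count Minimum total corpus occurrence count for a word to
#'   enter the vocabulary (default 5).
#' @param association `"npmi"` (default) or `"ppmi"`.
#' @param probability Probability space for the association table:
#'   `"document"` (default) or `"token"`; see [pmi()].
#' @param summation `"distinct"` (default) sums over distinct document
#'   words, with within-document multiplicity carried solely by the
#'   `n_word` factor inside tf-idf; `"per_token"` sums per token, which
#'   double-counts multiplicity, and is provided for comparison.
#' @param vocab Optional explicit vocabulary overriding the
#'   `min_count`-based construction (used by dictionary-size sweeps).
#' @param stopwords Stopword snapshot recorded in the model (used when
#'   tokenizing raw text at prediction time and serialized with the model).
#' @return An object of class `"ptic_model"`.
#' @export
#' @examples
#' corp <- tokenized_corpus(
#'   list(c("liver", "injury", "drug"), c("drug", "liver", "toxicity"),
#'        c("protein", "structure", "model"),
#'        c("model", "drug", "structure")),
#'   doc_id = c("d1", "d2", "d3", "d4"),
#'   label = c("pos", "pos", "neg", "neg"))
#' fit <- ptic_fit(corp, positive = "pos", min_count = 1)
#' classify(fit, corp)
ptic_fit <- function(corpus, positive = NULL, min_count = 5,
                     association = c("npmi", "ppmi"),
                     probability = c("document", "token"),
                     summation = c("distinct", "per_token"),
                     vocab = NULL, stopwords = ptic_stopwords()) {
  association <- match.arg(association)
  probability <- match.arg(probability)
  summation <- match.arg(summation)
  stopifnot(inherits(corpus, "tokenized_corpus"))
  classes <- sort(unique(corpus$label))
  if (length(classes) != 2) {
    stop("ptic_fit() requires exactly two classes; got: ",
         paste(classes, collapse = ", "))
  }
  positive <- resolve_positive(positive, classes)
  negative <- setdiff(classes, positive)
  if (is.null(vocab)) {
    vocab <- build_vocabulary(corpus, min_count)
  } else {
    # an explicit vocabulary may list words absent from this corpus; they
    # would make idf infinite, so drop them
    vocab <- intersect(sort(vocab),
                       unique(unlist(corpus$tokens, use.names = FALSE)))
  }
  if (length(vocab) == 0) stop("empty vocabulary after min_count filtering")
  counts <- count_table(corpus, vocab)
  if (any(counts$N_class == 0)) stop("a class has zero documents")

  assoc <- association_table(counts, probability)
  if (association == "ppmi") {
    assoc <- pmax(assoc$pmi_table, 0)
  } else {
    assoc <- assoc$npmi_table
  }

  structure(
    list(
      vocab = vocab,
      class_labels = c(positive, negative),
      positive = positive,
      negative = negative,
      assoc = assoc[c(positive, negative), , drop = FALSE],
      idf = log(counts$N / counts$N_word),
      priors = counts$N_class[c(positive, negative)] / counts$N,
      association_mode = association,
      probability_mode = probability,
      summation = summation,
      min_count = min_count,
      N = counts$N,
      N_word = counts$N_word,
      total_word_count = counts$total_word_count,
      stopwords = stopwords
    ),
    class = "ptic_model"
  )
}

resolve_positive <- function(positive, classes) {
  if (is.null(positive)) {
    if ("pos" %in% classes) return("pos")
    stop("specify `positive`: one of ", paste(classes, collapse = ", "))
  }
  if (!positive %in% classes) {
    stop("positive class '", positive, "' not among labels: ",
         paste(classes, collapse = ", "))
  }
  positive
}

# full npmi and pmi tables (classes x vocab) from a count table
association_table <- function(counts, probability = "document") {
  if (probability == "document") {
    P_cw <- counts$N_class_word / counts$N
    P_c <- counts$N_class / counts$N
    P_w <- counts$N_word / counts$N
  } else {
    tot <- sum(counts$tokens_per_class)
    P_cw <- counts$token_class_word / tot
    P_c <- counts$tokens_per_class / tot
    P_w <- Matrix::colSums(counts$token_class_word) / tot
  }
  pmi_table <- log(P_cw / outer(P_c, P_w))
  npmi_table <- ifelse(P_cw == 0, -1, pmi_table / (-log(P_cw)))
  pmi_table[P_cw == 0] <- -Inf
  list(pmi_table = pmi_table, npmi_table = npmi_table)
}

#' @export
print.ptic_model <- function(x, ...) {
  cat(sprintf(
    "PTIC model (%s, %s probabilities): %d words, classes %s (+) / %s (-)\n",
    x$association_mode, x$probability_mode, length(x$vocab),
    x$positive, x$negative))
  invisible(x)
}

# sparse tf-idf matrix (documents x model vocabulary); tf uses the full
# token count of each document, idf is the model's training-corpus table
tfidf_matrix <- function(model, corpus) {
  dtm <- dtm_from_tokens(corpus$tokens, model$vocab)
  n <- pmax(corpus$n, 1L)
  if (identical(model$summation, "per_token")) dtm <- dtm * dtm
  Matrix::Diagonal(x = 1 / n) %*% dtm %*% Matrix::Diagonal(x = model$idf)
}

#' Score documents under a PTIC model
#'
#' For each document and class `C`, computes
#' `F_C = sum over distinct in-vocabulary words of tf-idf(word) *
#' association(C, word)`. Out-of-vocabulary words contribute nothing; a
#' document with no in-vocabulary words scores 0 for every class.
#'
#' @param model A fitted [ptic_fit()] model.
#' @param corpus A [tokenized_corpus()] (labels not required).
#' @return Numeric matrix, one row per document, one column per class
#'   (positive first).
#' @export
ptic_score <- function(model, corpus) {
  stopifnot(inherits(model, "ptic_model"),
            inherits(corpus, "tokenized_corpus"))
  X <- tfidf_matrix(model, corpus)
  S <- as.matrix(X %*% t(model$assoc))
  dimnames(S) <- list(corpus$doc_id, model$class_labels)
  S
}

#' Classify documents with a fitted model
#'
#' Applies the model's decision rule and returns one row per document with
#' the class scores, the continuous decision margin, and the predicted
#' label. Ties (including documents with no in-vocabulary words) go to the
#' negative class: a tie is not evidence of the topic.
#'
#' @param model A fitted model ([ptic_fit()], [logit_ptic()] or
#'   [fit_nb()]).
#' @param corpus A [tokenized_corpus()].
#' @param ... Passed to the model-specific method (e.g. `threshold` for
#'   logit PTIC).
#' @return Data frame with columns `doc_id`, `score_pos`, `score_neg`,
#'   `margin`, `predicted`.
#' @export
classify <- function(model, corpus, ...) UseMethod("classify")

#' @rdname classify
#' @export
classify.ptic_model <- function(model, corpus, ...) {
  S <- ptic_score(model, corpus)
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
predict.ptic_model <- function(object, newdata, ...) {
  classify.ptic_model(object, newdata, ...)
}

#' Per-document word contributions (explainability)
#'
#' Decomposes a document's decision margin into per-word contributions
#' `tf-idf(word) * (assoc(pos, word) - assoc(neg, word))`, ranked by
#' absolute magnitude.
#'
#' @param model A fitted [ptic_fit()] model.
#' @param doc Character vector of document tokens.
#' @return Data frame with columns `word`, `tfidf`, `assoc_pos`,
#'   `assoc_neg`, `contribution`, sorted by `abs(contribution)` descending.
#' @export
explain <- function(model, doc) {
  stopifnot(inherits(model, "ptic_model"))
  words <- intersect(unique(doc), model$vocab)
  if (length(words) == 0) {
    return(data.frame(word = character(), tfidf = numeric(),
                      assoc_pos = numeric(), assoc_neg = numeric(),
                      contribution = numeric()))
  }
  n <- length(doc)
  nw <- vapply(words, function(w) sum(doc == w), numeric(1))
  if (identical(model$summation, "per_token")) nw <- nw^2
  tfidf <- nw * (1 / n) * model$idf[words]
  ap <- model$assoc[model$positive, words]
  an <- model$assoc[model$negative, words]
  out <- data.frame(word = words, tfidf = tfidf, assoc_pos = ap,
                    assoc_neg = an, contribution = tfidf * (ap - an),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-abs(out$contribution)), , drop = FALSE]
}

#' Numerical error of the Shannon-information form of npmi
#'
#' npmi can equivalently be written in Shannon information terms as
#' `(h(A) + h(B) - h(A,B)) / h(A,B)` with `h(x) = -log p(x)`. This
#' returns the absolute difference between the direct and the
#' information-form evaluation; it exists to support property tests of the
#' algebraic identity and requires all three probabilities to be strictly
#' positive.
#'
#' @inheritParams pmi
#' @return Non-negative numeric scalar (machine-precision small wherever
#'   the identity is defined).
#' @export
shannon_identity_error <- function(counts, class, word,
                                   probability = c("document", "token")) {
  probability <- match.arg(probability)
  p <- joint_probs(counts, class, word, probability)
  if (p$joint <= 0 || p$class <= 0 || p$word <= 0) {
    stop("identity undefined: zero probability")
  }
  h <- function(x) -log(x)
  direct <- npmi(counts, class, word, probability)
  info_form <- (h(p$class) + h(p$word) - h(p$joint)) / h(p$joint)
  abs(direct - info_form)
}

#' Restrict a fitted PTIC model to its top-k dictionary words
#'
#' Implements dictionary-size control: keeps the `k` highest-ranked
#' vocabulary words and drops the rest from the association and idf
#' tables. Ranking is by total corpus frequency (default) or by the
#' largest absolute association score across classes.
#'
#' @param model A fitted [ptic_fit()] model.
#' @param k Number of words to keep (capped at the vocabulary size).
#' @param by `"frequency"` (default) or `"npmi"`.
#' @return A `"ptic_model"` with the restricted vocabulary.
#' @export
shrink_vocabulary <- function(model, k, by = c("frequency", "npmi")) {
  by <- match.arg(by)
  stopifnot(inherits(model, "ptic_model"), k >= 1)
  k <- min(k, length(model$vocab))
  rank_key <- switch(by,
    frequency = model$total_word_count[model$vocab],
    npmi = apply(abs(model$assoc), 2, max)
  )
  keep <- model$vocab[order(-rank_key, model$vocab)][seq_len(k)]
  keep <- sort(keep)
  model$vocab <- keep
  model$assoc <- model$assoc[, keep, drop = FALSE]
  model$idf <- model$idf[keep]
  model$N_word <- model$N_word[keep]
  model$total_word_count <- model$total_word_count[keep]
  model
}
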