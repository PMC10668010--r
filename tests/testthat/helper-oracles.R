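# Independent brute-force oracles: everything here works directly from raw
# token lists with plain loops and the defining formulas, never through the
# package's count/fit machinery, so tests compare two independent routes.

t4_tokens <- list(
  d1 = c("liver", "injury", "drug"),
  d2 = c("drug", "liver", "toxicity"),
  d3 = c("protein", "structure", "model"),
  d4 = c("model", "drug", "structure")
)
t4_labels <- c("pos", "pos", "neg", "neg")

t4_corpus <- function() {
  tokenized_corpus(unname(t4_tokens), doc_id = names(t4_tokens),
                   label = t4_labels)
}

# document-level probabilities by direct enumeration
oracle_probs <- function(tokens, labels, class, word) {
  in_doc <- vapply(tokens, function(d) word %in% d, logical(1))
  list(
    joint = sum(in_doc & labels == class) / length(tokens),
    class = sum(labels == class) / length(tokens),
    word = sum(in_doc) / length(tokens)
  )
}

oracle_pmi <- function(tokens, labels, class, word) {
  p <- oracle_probs(tokens, labels, class, word)
  log(p$joint / (p$class * p$word))
}

oracle_npmi <- function(tokens, labels, class, word) {
  p <- oracle_probs(tokens, labels, class, word)
  if (p$joint == 0) return(-1)
  log(p$joint / (p$class * p$word)) / (-log(p$joint))
}

oracle_tf_idf <- function(doc, word, tokens) {
  N <- length(tokens)
  N_word <- sum(vapply(tokens, function(d) word %in% d, logical(1)))
  sum(doc == word) * (1 / length(doc)) * log(N / N_word)
}

# PTIC class score by direct summation over the document's distinct words
oracle_ptic_score <- function(doc, class, tokens, labels, vocab) {
  total <- 0
  for (w in intersect(unique(doc), vocab)) {
    total <- total + oracle_tf_idf(doc, w, tokens) *
      oracle_npmi(tokens, labels, class, w)
  }
  total
}

# normalized NB posterior P(c | doc) by direct evaluation of the smoothed
# multinomial model, with explicit per-class products
oracle_nb_posterior <- function(doc, tokens, labels, vocab, alpha = 1) {
  classes <- sort(unique(labels))
  log_scores <- vapply(classes, function(cl) {
    class_tokens <- unlist(tokens[labels == cl], use.names = FALSE)
    class_tokens <- class_tokens[class_tokens %in% vocab]
    s <- log(sum(labels == cl) / length(labels))
    for (tok in doc) {
      if (tok %in% vocab) {
        s <- s + log((sum(class_tokens == tok) + alpha) /
                       (length(class_tokens) + alpha * length(vocab)))
      }
    }
    s
  }, numeric(1))
  post <- exp(log_scores - max(log_scores))
  setNames(post / sum(post), classes)
}

# small random corpus of plain token lists (for property tests)
random_token_corpus <- function(n_docs, words, max_len = 8, seed = 1) {
  set.seed(seed)
  tokens <- lapply(seq_len(n_docs), function(i)
    sample(words, sample(1:max_len, 1), replace = TRUE))
  labels <- sample(c("pos", "neg"), n_docs, replace = TRUE)
  # guarantee both classes
  labels[1] <- "pos"; labels[2] <- "neg"
  tokenized_corpus(tokens, label = labels)
}
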