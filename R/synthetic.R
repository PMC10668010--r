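#' Configuration for the synthetic corpus generator
#'
#' Describes the full generative recipe for labeled title+abstract
#' corpora with the statistical structure the classifier assumes:
#' class-indicative signal words mixed into shared background vocabulary.
#' Per document, a class label is drawn (exact counts, then shuffled), a
#' token count is drawn from a negative-binomial distribution (minimum 1;
#' abstract lengths are over-dispersed), and each token is, independently,
#' a uniformly chosen signal word of the document's class with probability
#' `signal_prob`, otherwise a background word drawn from a Zipf
#' rank-frequency profile (so idf varies realistically across the
#' vocabulary). Finally a fraction of labels is flipped uniformly at
#' random. Identical configs generate identical corpora.
#'
#' @param n_docs Number of documents.
#' @param positive_fraction Fraction of documents labeled positive, in
#'   (0, 1); realized as exact counts.
#' @param vocab_background Number of background words shared by both
#'   classes.
#' @param signal_words_per_class Number of class-exclusive signal words
#'   per class.
#' @param signal_prob Per-token probability of emitting a signal word of
#'   the document's class.
#' @param doc_length_mean,doc_length_size Mean and dispersion (negative
#'   binomial `size`) of document token counts; minimum length 1.
#' @param label_noise_fraction Fraction of labels flipped after
#'   generation, in \[0, 1).
#' @param zipf_exponent Exponent of the background rank-frequency profile
#'   (probability of rank r proportional to `1 / r^s`).
#' @param seed Integer seed; the config is the complete recipe.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_docs = 1000, positive_fraction = 0.5,
                             vocab_background = 500,
                             signal_words_per_class = 20,
                             signal_prob = 0.1,
                             doc_length_mean = 60, doc_length_size = 10,
                             label_noise_fraction = 0,
                             zipf_exponent = 1, seed = 1) {
  cfg <- list(n_docs = as.integer(n_docs),
              positive_fraction = positive_fraction,
              vocab_background = as.integer(vocab_background),
              signal_words_per_class = as.integer(signal_words_per_class),
              signal_prob = signal_prob,
              doc_length_mean = doc_length_mean,
              doc_length_size = doc_length_size,
              label_noise_fraction = label_noise_fraction,
              zipf_exponent = zipf_exponent,
              seed = as.integer(seed))
  if (cfg$n_docs < 2) stop("n_docs must be at least 2")
  if (cfg$positive_fraction <= 0 || cfg$positive_fraction >= 1) {
    stop("positive_fraction must lie in (0, 1)")
  }
  n_pos <- round(cfg$positive_fraction * cfg$n_docs)
  if (n_pos < 1 || n_pos > cfg$n_docs - 1) {
    stop("config implies a class with no documents")
  }
  if (cfg$vocab_background < 1 || cfg$signal_words_per_class < 1) {
    stop("vocabulary sizes must be >= 1")
  }
  if (cfg$signal_prob < 0 || cfg$signal_prob > 1) {
    stop("signal_prob must lie in [0, 1]")
  }
  if (cfg$label_noise_fraction < 0 || cfg$label_noise_fraction >= 1) {
    stop("label_noise_fraction must lie in [0, 1)")
  }
  if (cfg$doc_length_mean <= 0 || cfg$doc_length_size <= 0) {
    stop("document length parameters must be positive")
  }
  structure(cfg, class = "synthetic_config")
}

# deterministic purely-alphabetic word ids: prefix + base-26 suffix
make_words <- function(prefix, k) {
  suffix <- character(k)
  for (i in seq_len(k)) {
    v <- i - 1L
    s <- ""
    repeat {
      s <- paste0(letters[v %% 26L + 1L], s)
      v <- v %/% 26L
      if (v == 0L) break
      v <- v - 1L
    }
    suffix[i] <- s
  }
  paste0(prefix, suffix)
}

#' Generate a labeled synthetic corpus
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `doc_id`, `title`, `abstract`, `label`
#'   (the same format [read_corpus()] consumes); the first few tokens form
#'   the title, the rest the abstract. All generated words are lowercase
#'   alphabetic and survive [tokenize()] unchanged.
#' @export
#' @examples
#' corp <- generate_corpus(synthetic_config(n_docs = 10, seed = 42))
#' head(corp$label)
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_docs
  n_pos <- round(config$positive_fraction * n)
  labels <- sample(c(rep("pos", n_pos), rep("neg", n - n_pos)))
  lens <- pmax(1L, rnbinom(n, mu = config$doc_length_mean,
                           size = config$doc_length_size))
  bg <- make_words("bg", config$vocab_background)
  bg_prob <- 1 / seq_along(bg)^config$zipf_exponent
  bg_prob <- bg_prob / sum(bg_prob)
  sig <- list(pos = make_words("sigp", config$signal_words_per_class),
              neg = make_words("sign", config$signal_words_per_class))
  title <- character(n)
  abstract <- character(n)
  for (i in seq_len(n)) {
    m <- lens[i]
    toks <- sample(bg, m, replace = TRUE, prob = bg_prob)
    is_sig <- runif(m) < config$signal_prob
    if (any(is_sig)) {
      toks[is_sig] <- sample(sig[[labels[i]]], sum(is_sig), replace = TRUE)
    }
    nt <- min(5L, m)
    title[i] <- paste(toks[seq_len(nt)], collapse = " ")
    abstract[i] <- if (m > nt) {
      paste(toks[(nt + 1L):m], collapse = " ")
    } else ""
  }
  corpus <- data.frame(doc_id = sprintf("doc%06d", seq_len(n)),
                       title = title, abstract = abstract, label = labels,
                       stringsAsFactors = FALSE)
  if (config$label_noise_fraction > 0) {
    corpus <- inject_label_noise(corpus, config$label_noise_fraction,
                                 seed = config$seed + 1L)
  }
  corpus
}

#' Enlarge the negative pool of a corpus
#'
#' Emulates increasingly imbalanced test sets: the negative documents are
#' resampled with replacement (seeded) until their count is `multiplier`
#' times the original, while positive documents are left untouched.
#' Resampled rows get fresh unique ids.
#'
#' @param corpus Labeled corpus data frame.
#' @param multiplier Negative-pool multiplier (>= 1).
#' @param seed Integer seed.
#' @return Corpus data frame; original rows first, resampled negatives
#'   appended.
#' @export
rebalance <- function(corpus, multiplier, seed = 1) {
  if (multiplier < 1) stop("multiplier must be >= 1")
  if (multiplier == 1) return(corpus)
  neg_idx <- which(corpus$label != "pos")
  n_extra <- round((multiplier - 1) * length(neg_idx))
  if (n_extra == 0) return(corpus)
  set.seed(seed)
  extra <- corpus[sample(neg_idx, n_extra, replace = TRUE), , drop = FALSE]
  extra$doc_id <- sprintf("%s_rs%06d", extra$doc_id, seq_len(n_extra))
  out <- rbind(corpus, extra)
  rownames(out) <- NULL
  out
}

#' Flip a fixed fraction of labels uniformly at random
#'
#' Exactly `round(fraction * n)` documents, chosen uniformly with the
#' seed, have their labels flipped (`pos` <-> `neg`). Applying the same
#' fraction and seed twice flips the same set, restoring the original
#' labels.
#'
#' @param corpus Labeled corpus data frame.
#' @param fraction Fraction of labels to flip, in \[0, 1).
#' @param seed Integer seed.
#' @return Corpus data frame with flipped labels.
#' @export
inject_label_noise <- function(corpus, fraction, seed = 1) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  k <- round(fraction * nrow(corpus))
  if (k == 0) return(corpus)
  set.seed(seed)
  idx <- sample.int(nrow(corpus), k)
  corpus$label[idx] <- ifelse(corpus$label[idx] == "pos", "neg", "pos")
  corpus
}

#' Stratified train/test split of a corpus
#'
#' Splits a labeled corpus into train and test portions, sampling the test
#' set within each class so both classes are represented on both sides.
#'
#' @param corpus Labeled corpus data frame.
#' @param test_fraction Fraction of each class held out (default 0.2).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_corpus <- function(corpus, test_fraction = 0.2, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  set.seed(seed)
  test_idx <- unlist(lapply(split(seq_len(nrow(corpus)), corpus$label),
                            function(idx) {
                              k <- max(1L, round(test_fraction * length(idx)))
                              sample(idx, k)
                            }), use.names = FALSE)
  list(train = corpus[-test_idx, , drop = FALSE],
       test = corpus[test_idx, , drop = FALSE])
}
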