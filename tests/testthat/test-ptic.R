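t4 <- t4_corpus()
t4_vocab <- build_vocabulary(t4, 1)
t4_ct <- count_table(t4, t4_vocab)

test_that("pmi/npmi/ppmi agree with the brute-force oracle on the toy corpus", {
  for (cl in c("pos", "neg")) {
    for (w in t4_vocab) {
      o_pmi <- oracle_pmi(t4_tokens, t4_labels, cl, w)
      if (is.finite(o_pmi)) {
        expect_equal(pmi(t4_ct, cl, w), o_pmi, tolerance = 1e-12)
        expect_equal(ppmi(t4_ct, cl, w), max(o_pmi, 0), tolerance = 1e-12)
      } else {
        expect_identical(pmi(t4_ct, cl, w), -Inf)
        expect_identical(ppmi(t4_ct, cl, w), 0)
      }
      expect_equal(npmi(t4_ct, cl, w),
                   oracle_npmi(t4_tokens, t4_labels, cl, w),
                   tolerance = 1e-12)
    }
  }
  # frozen hand values
  expect_equal(pmi(t4_ct, "pos", "drug"), log(4 / 3), tolerance = 1e-12)
  expect_equal(pmi(t4_ct, "pos", "liver"), log(2), tolerance = 1e-12)
  expect_equal(npmi(t4_ct, "pos", "liver"), 1, tolerance = 1e-12)
  expect_equal(npmi(t4_ct, "pos", "drug"), log(4 / 3) / log(2),
               tolerance = 1e-12)
  expect_identical(npmi(t4_ct, "neg", "liver"), -1)
})

test_that("pmi is zero for a word statistically independent of the class", {
  # both docs of each class contain "shared"; P(c,w) = P(c) * P(w)
  corp <- tokenized_corpus(list(c("shared", "a"), c("shared", "b"),
                                c("shared", "c"), c("shared", "d")),
                           label = c("pos", "pos", "neg", "neg"))
  ct <- count_table(corp, build_vocabulary(corp, 1))
  expect_equal(pmi(ct, "pos", "shared"), 0, tolerance = 1e-12)
  expect_equal(npmi(ct, "pos", "shared"), 0, tolerance = 1e-12)
})

test_that("tf_idf evaluates its defining formula", {
  expect_equal(tf_idf(t4_tokens$d1, "drug", t4_ct), (1 / 3) * log(4 / 3),
               tolerance = 1e-12)
  expect_equal(tf_idf(t4_tokens$d1, "drug", t4_ct),
               oracle_tf_idf(t4_tokens$d1, "drug", t4_tokens),
               tolerance = 1e-12)
  # absent word contributes zero
  expect_equal(tf_idf(t4_tokens$d3, "drug", t4_ct), 0)
  expect_error(tf_idf(t4_tokens$d1, "nonword", t4_ct), "vocabulary")
  # word occurring twice in a 4-token doc, sole containing document
  corp <- tokenized_corpus(list(c("x", "x", "y", "z"), c("y"), c("z"),
                                c("y", "z")),
                           label = c("pos", "neg", "neg", "pos"))
  ct <- count_table(corp, build_vocabulary(corp, 1))
  expect_equal(tf_idf(corp$tokens[[1]], "x", ct), 2 * (1 / 4) * log(4),
               tolerance = 1e-12)
  # a word present in every document has idf 0
  corp2 <- tokenized_corpus(list(c("w", "a"), c("w", "b")),
                            label = c("pos", "neg"))
  ct2 <- count_table(corp2, build_vocabulary(corp2, 1))
  expect_equal(tf_idf(c("w", "a"), "w", ct2), 0)
})

test_that("fitted npmi table is bounded and hits its boundary cases", {
  m <- ptic_fit(t4, min_count = 1)
  expect_true(all(m$assoc >= -1 & m$assoc <= 1))
  expect_equal(m$assoc["pos", "liver"], 1)
  expect_equal(m$assoc["neg", "liver"], -1)
  expect_equal(sum(m$priors), 1)
  expect_true(all(m$idf >= 0))
  # ppmi variant is non-negative and equals max(pmi, 0)
  mp <- ptic_fit(t4, min_count = 1, association = "ppmi")
  expect_true(all(mp$assoc >= 0))
  expect_equal(mp$assoc["pos", "drug"], log(4 / 3), tolerance = 1e-12)
  expect_equal(mp$assoc["neg", "liver"], 0)
})

test_that("fitting on identically distributed classes gives near-zero npmi", {
  docs <- replicate(20, c("alpha", "beta", "gamma"), simplify = FALSE)
  corp <- tokenized_corpus(docs, label = rep(c("pos", "neg"), 10))
  m <- ptic_fit(corp, min_count = 1)
  expect_true(all(abs(m$assoc) < 1e-10))
})

test_that("scores match hand summation and drive the argmax decision", {
  m <- ptic_fit(t4, min_count = 1)
  S <- ptic_score(m, t4)
  for (i in 1:4) {
    for (cl in c("pos", "neg")) {
      expect_equal(S[i, cl],
                   oracle_ptic_score(t4$tokens[[i]], cl, t4_tokens,
                                     t4_labels, t4_vocab),
                   tolerance = 1e-12)
    }
  }
  pred <- classify(m, t4)
  expect_equal(pred$predicted, c("pos", "pos", "neg", "neg"))
  expect_true(pred$margin[1] > 0)
  expect_equal(pred$margin, pred$score_pos - pred$score_neg)
})

test_that("empty and out-of-vocabulary documents score zero and tie to negative", {
  m <- ptic_fit(t4, min_count = 1)
  odd <- tokenized_corpus(list(character(), c("unseen", "words")),
                          doc_id = c("e1", "e2"))
  pred <- classify(m, odd)
  expect_equal(pred$score_pos, c(0, 0))
  expect_equal(pred$score_neg, c(0, 0))
  expect_equal(pred$predicted, c("neg", "neg"))
})

test_that("score is invariant to token order (bag of words)", {
  m <- ptic_fit(t4, min_count = 1)
  doc <- c("liver", "drug", "model", "liver", "structure")
  for (seed in 1:5) {
    set.seed(seed)
    shuffled <- sample(doc)
    expect_equal(
      ptic_score(m, tokenized_corpus(list(doc))),
      ptic_score(m, tokenized_corpus(list(shuffled))),
      ignore_attr = TRUE
    )
  }
})

test_that("adding a positively associated word never decreases the margin", {
  m <- ptic_fit(t4, min_count = 1)
  # "liver": npmi[pos] = 1 > 0, npmi[neg] = -1 < 0
  doc <- c("drug", "model", "structure")
  base_margin <- classify(m, tokenized_corpus(list(doc)))$margin
  for (extra in 1:4) {
    doc <- c(doc, "liver")
    margin <- classify(m, tokenized_corpus(list(doc)))$margin
    expect_gte(margin, base_margin)
    base_margin <- margin
  }
})

test_that("held-out accuracy is perfect on a class-separable synthetic corpus", {
  cfg <- synthetic_config(n_docs = 500, signal_prob = 0.3,
                          doc_length_mean = 40, seed = 11)
  parts <- split_corpus(generate_corpus(cfg), 0.2, seed = 12)
  m <- ptic_fit(tokenize_corpus(parts$train))
  tc_test <- tokenize_corpus(parts$test)
  pred <- classify(m, tc_test)
  expect_equal(mean(pred$predicted == tc_test$label), 1.0)
})

test_that("shannon information identity holds wherever defined", {
  for (cl in c("pos", "neg")) {
    for (w in t4_vocab) {
      if (t4_ct$N_class_word[cl, w] > 0) {
        expect_lt(shannon_identity_error(t4_ct, cl, w), 1e-12)
      } else {
        expect_error(shannon_identity_error(t4_ct, cl, w), "undefined")
      }
    }
  }
})

test_that("token-level probability space is a coherent alternative", {
  m_doc <- ptic_fit(t4, min_count = 1, probability = "document")
  m_tok <- ptic_fit(t4, min_count = 1, probability = "token")
  expect_true(all(m_tok$assoc >= -1 & m_tok$assoc <= 1))
  # both spaces agree on the toy corpus labels
  expect_equal(classify(m_tok, t4)$predicted, classify(m_doc, t4)$predicted)
})

test_that("per-token summation squares multiplicity relative to distinct-word", {
  m <- ptic_fit(t4, min_count = 1)
  m_pt <- ptic_fit(t4, min_count = 1, summation = "per_token")
  doc <- tokenized_corpus(list(c("liver", "liver", "drug")))
  s_d <- ptic_score(m, doc)
  s_pt <- ptic_score(m_pt, doc)
  # contribution of "liver" (count 2) is doubled again under per_token;
  # "drug" (count 1) is unchanged
  idf <- m$idf
  a <- m$assoc
  expect_equal(s_pt[1, "pos"] - s_d[1, "pos"],
               (4 - 2) * (1 / 3) * idf[["liver"]] * a["pos", "liver"],
               tolerance = 1e-12)
})

test_that("serialization round-trips to bitwise-identical predictions", {
  m <- ptic_fit(t4, min_count = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(ptic_score(m2, t4), ptic_score(m, t4))
  expect_identical(m2$stopwords, m$stopwords)
  expect_equal(m2$assoc, m$assoc)
})

test_that("explain decomposes the decision margin exactly", {
  m <- ptic_fit(t4, min_count = 1)
  doc <- c("liver", "drug", "model", "liver")
  ex <- explain(m, doc)
  pred <- classify(m, tokenized_corpus(list(doc)))
  expect_equal(sum(ex$contribution), pred$margin, tolerance = 1e-12)
  expect_true(all(diff(abs(ex$contribution)) <= 1e-15))
  expect_equal(nrow(explain(m, c("unknown"))), 0)
})

test_that("shrink_vocabulary keeps top-k words and is the identity at full k", {
  m <- ptic_fit(t4, min_count = 1)
  full <- shrink_vocabulary(m, length(m$vocab))
  expect_identical(ptic_score(full, t4), ptic_score(m, t4))
  m1 <- shrink_vocabulary(m, 1, by = "frequency")
  expect_equal(m1$vocab, "drug")  # highest total count in T4
  m_npmi <- shrink_vocabulary(m, 2, by = "npmi")
  expect_true(all(apply(abs(m_npmi$assoc), 2, max) == 1))
})

test_that("fit validates its inputs", {
  expect_error(ptic_fit(tokenized_corpus(list(c("a")), label = "pos")),
               "two classes")
  three <- tokenized_corpus(list(c("a"), c("b"), c("c")),
                            label = c("x", "y", "z"))
  expect_error(ptic_fit(three), "two classes")
  ab <- tokenized_corpus(list(c("aa", "bb"), c("bb", "cc")),
                         label = c("x", "y"))
  expect_error(ptic_fit(ab, min_count = 1), "positive")
  expect_silent(ptic_fit(ab, positive = "x", min_count = 1))
})
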