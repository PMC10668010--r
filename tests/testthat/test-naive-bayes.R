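t4 <- t4_corpus()

test_that("smoothed conditional probabilities match hand counts on T4", {
  nb <- fit_nb(t4, alpha = 1, min_count = 1)
  expect_equal(exp(nb$log_cond["pos", "liver"]), 3 / 13, tolerance = 1e-12)
  expect_equal(exp(nb$log_cond["neg", "liver"]), 1 / 13, tolerance = 1e-12)
  expect_equal(nb$log_prior[["pos"]], log(0.5), tolerance = 1e-12)
  # smoothing: nothing is -Inf, and each class's conditionals sum to 1
  expect_true(all(is.finite(nb$log_cond)))
  expect_equal(unname(rowSums(exp(nb$log_cond))), c(1, 1),
               tolerance = 1e-12)
  expect_equal(sum(exp(nb$log_prior)), 1, tolerance = 1e-12)
})

test_that("log posteriors follow priors and token multiplicity", {
  nb <- fit_nb(t4, alpha = 1, min_count = 1)
  # empty doc: scores equal the log priors
  S <- nb_log_posterior(nb, tokenized_corpus(list(character())))
  expect_equal(unname(S[1, ]), unname(nb$log_prior), tolerance = 1e-12)
  # out-of-vocab-only doc: priors decide
  S2 <- nb_log_posterior(nb, tokenized_corpus(list(c("qqq", "zzz"))))
  expect_equal(unname(S2[1, ]), unname(nb$log_prior), tolerance = 1e-12)
  # d1 scores positive
  pred <- classify(nb, t4)
  expect_equal(pred$predicted, c("pos", "pos", "neg", "neg"))
  expect_gt(pred$score_pos[1], pred$score_neg[1])
})

test_that("a class-symmetric document produces an exact score tie", {
  corp <- tokenized_corpus(list(c("aa", "bb"), c("cc", "dd")),
                           label = c("pos", "neg"))
  nb <- fit_nb(corp, alpha = 1, min_count = 1)
  # one word from each class's vocabulary, equal priors
  S <- nb_log_posterior(nb, tokenized_corpus(list(c("aa", "cc"))))
  expect_lt(abs(S[1, "pos"] - S[1, "neg"]), 1e-12)
  # ties go to the negative class
  expect_equal(classify(nb, tokenized_corpus(list(c("aa", "cc"))))$predicted,
               "neg")
})

test_that("classifier agrees with direct posterior evaluation on enumerated corpora", {
  # exhaustive small-instance oracle: every corpus of 2 documents over 4
  # words and of 3 documents over 3 words, with presence/absence documents
  # and every labeling that uses both classes
  check_corpus <- function(docs, labels) {
    corp <- tokenized_corpus(docs, label = labels)
    vocab <- build_vocabulary(corp, 1)
    nb <- fit_nb(corp, alpha = 1, min_count = 1)
    pred <- classify(nb, corp)
    S <- nb_log_posterior(nb, corp)
    for (i in seq_along(docs)) {
      post <- oracle_nb_posterior(docs[[i]], docs, labels, vocab,
                                  alpha = 1)
      # normalized posteriors from the package scores
      pkg_post <- exp(S[i, ] - max(S[i, ]))
      pkg_post <- pkg_post / sum(pkg_post)
      expect_equal(pkg_post[["pos"]], post[["pos"]], tolerance = 1e-12)
      expect_equal(sum(pkg_post), 1, tolerance = 1e-12)
      diff <- post[["pos"]] - post[["neg"]]
      if (abs(diff) > 1e-9) {
        # clear of exact ties, the two routes must agree on the label
        expect_identical(pred$predicted[i], if (diff > 0) "pos" else "neg")
      } else {
        # numerical tie: the package must also see (near-)zero margin
        expect_lt(abs(S[i, "pos"] - S[i, "neg"]), 1e-9)
      }
    }
  }
  subsets <- function(words) {
    pats <- Filter(length, lapply(1:(2^length(words) - 1), function(mask) {
      words[bitwAnd(mask, 2^(seq_along(words) - 1)) > 0]
    }))
    pats
  }
  pats4 <- subsets(c("wa", "wb", "wc", "wd"))
  for (i in seq_along(pats4)) {
    for (j in seq_along(pats4)) {
      check_corpus(list(pats4[[i]], pats4[[j]]), c("pos", "neg"))
    }
  }
  pats3 <- subsets(c("wa", "wb", "wc"))
  labelings <- list(c("pos", "pos", "neg"), c("pos", "neg", "pos"),
                    c("neg", "pos", "pos"), c("neg", "neg", "pos"),
                    c("neg", "pos", "neg"), c("pos", "neg", "neg"))
  for (i in seq_along(pats3)) {
    for (j in seq_along(pats3)) {
      for (k in seq_along(pats3)) {
        for (lab in labelings) {
          check_corpus(list(pats3[[i]], pats3[[j]], pats3[[k]]), lab)
        }
      }
    }
  }
})

test_that("duplicating positive documents shifts the prior by log k", {
  docs <- list(c("aa", "bb"), c("bb", "cc"), c("cc", "dd"))
  labels <- c("pos", "neg", "neg")
  corp1 <- tokenized_corpus(docs, label = labels)
  k <- 3
  corp_k <- tokenized_corpus(c(rep(docs[1], k), docs[2:3]),
                             label = c(rep("pos", k), "neg", "neg"))
  nb1 <- fit_nb(corp1, min_count = 1)
  nbk <- fit_nb(corp_k, min_count = 1)
  # the prior shifts by exactly log((k/(k+2)) / (1/3)); the conditionals
  # also change (the positive token pool is duplicated), which the
  # brute-force oracle captures
  expect_equal(nbk$log_prior[["pos"]] - nb1$log_prior[["pos"]],
               log(3 / 5) - log(1 / 3), tolerance = 1e-12)
  vocab <- build_vocabulary(corp_k, 1)
  d <- c("bb")
  post <- oracle_nb_posterior(d, corp_k$tokens, corp_k$label, vocab)
  S <- nb_log_posterior(nbk, tokenized_corpus(list(d)))
  pkg_post <- exp(S[1, ] - max(S[1, ]))
  pkg_post <- pkg_post / sum(pkg_post)
  expect_equal(pkg_post[["pos"]], post[["pos"]], tolerance = 1e-12)
})

test_that("nb serialization round-trips and inputs are validated", {
  nb <- fit_nb(t4, min_count = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(nb, path)
  back <- read_model(path)
  expect_identical(nb_log_posterior(back, t4), nb_log_posterior(nb, t4))
  expect_error(fit_nb(t4, alpha = 0, min_count = 1))
  expect_error(fit_nb(tokenized_corpus(list(c("a")), label = "pos")),
               "two classes")
})
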