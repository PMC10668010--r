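# max relative error between the analytic loss gradient and central finite
# differences, over sampled weight entries on a seeded synthetic corpus
grad_check_max_err <- function(loss, seed = 13, n_entries = 12) {
  cfg_data <- synthetic_config(n_docs = 60, signal_prob = 0.2,
                               doc_length_mean = 20, seed = seed)
  tc <- tokenize_corpus(generate_corpus(cfg_data))
  base <- ptic_fit(tc, min_count = 2)
  X <- pticlass:::tfidf_matrix(base, tc)
  y <- as.numeric(tc$label == base$positive)
  ap <- base$assoc[base$positive, ]
  an <- base$assoc[base$negative, ]
  fp <- focal_params()
  set.seed(seed)
  W <- matrix(runif(2 * length(ap), 0.5, 1.5), 2)
  lg <- pticlass:::logit_loss_grad(W, X, y, ap, an, loss, fp)
  h <- 1e-6
  errs <- vapply(seq_len(n_entries), function(k) {
    i <- sample(1:2, 1); j <- sample(ncol(W), 1)
    Wp <- W; Wp[i, j] <- W[i, j] + h
    Wm <- W; Wm[i, j] <- W[i, j] - h
    num <- (pticlass:::logit_loss_grad(Wp, X, y, ap, an, loss, fp)$loss -
              pticlass:::logit_loss_grad(Wm, X, y, ap, an, loss, fp)$loss) /
      (2 * h)
    ana <- lg$grad[i, j]
    abs(num - ana) / max(abs(num), abs(ana), 1e-8)
  }, numeric(1))
  max(errs)
}
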