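#' Training configuration for logit PTIC
#'
#' Defaults follow the method's standard recipe: 1,000 epochs, batch size
#' 100, adaptive-moment (Adam) gradient descent with learning rate 1e-5.
#'
#' @param epochs Number of passes over the training data (>= 1).
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Step size (> 0).
#' @param loss `"cross_entropy"` (default) or `"focal"`.
#' @param focal A [focal_params()] list, used when `loss = "focal"`.
#' @param seed Integer seed driving mini-batch shuffling (and any other
#'   randomness); identical seeds give identical trained weights.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 1000, batch_size = 100,
                         learning_rate = 1e-5,
                         loss = c("cross_entropy", "focal"),
                         focal = focal_params(), seed = 1) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 focal = focal, seed = as.integer(seed)),
            class = "train_config")
}

#' Focal loss parameters
#'
#' @param gamma Focusing parameter (>= 0); 2 is the standard choice.
#' @param alpha_pos Balancing factor for the positive class in (0, 1);
#'   default 0.3.
#' @param alpha_neg Balancing factor for the negative class; defaults to
#'   `1 - alpha_pos`.
#' @return A list of class `"focal_params"`.
#' @export
focal_params <- function(gamma = 2, alpha_pos = 0.3,
                         alpha_neg = 1 - alpha_pos) {
  stopifnot(gamma >= 0, alpha_pos > 0, alpha_pos < 1, alpha_neg > 0)
  structure(list(gamma = gamma, alpha_pos = alpha_pos,
                 alpha_neg = alpha_neg),
            class = "focal_params")
}

#' Focal loss
#'
#' `FL(p_t) = -alpha_t * (1 - p_t)^gamma * log(p_t)` where `p_t` is the
#' predicted probability of the true class. With `gamma = 0` and
#' `alpha_t = 1` this reduces exactly to cross-entropy `-log(p_t)`; for
#' `gamma > 0` easy examples (`p_t` near 1) are down-weighted, focusing
#' training on the hard ones.
#'
#' @param p_t Probability of the true class, in (0, 1]; vectorized.
#' @param gamma Focusing parameter (>= 0).
#' @param alpha_t Balancing factor for the true class.
#' @return Numeric vector of non-negative losses.
#' @export
#' @examples
#' focal_loss(0.5, gamma = 2, alpha_t = 0.3)
focal_loss <- function(p_t, gamma = 2, alpha_t = 0.3) {
  stopifnot(gamma >= 0)
  if (any(p_t <= 0) || any(p_t > 1)) {
    stop("p_t must lie in (0, 1]: infinite loss at p_t = 0")
  }
  -alpha_t * (1 - p_t)^gamma * log(p_t)
}

#' Initialize a logit PTIC model from a fitted PTIC base
#'
#' Attaches one trainable weight per (class, word), initialized to 1
#' everywhere so that the untrained model reproduces the base PTIC
#' decision exactly: the logit is the weighted positive-class score minus
#' the weighted negative-class score, passed through a sigmoid, and at
#' `W == 1` its sign equals the sign of the PTIC margin.
#'
#' @param base A fitted [ptic_fit()] model.
#' @return An object of class `"logit_ptic"` with fields `base`, `W`
#'   (2 x vocabulary weight matrix, rows positive/negative), and `trace`
#'   (per-epoch mean training loss, empty until trained).
#' @export
logit_ptic <- function(base) {
  stopifnot(inherits(base, "ptic_model"))
  W <- matrix(1, 2, length(base$vocab),
              dimnames = list(base$class_labels, base$vocab))
  structure(list(base = base, W = W, trace = numeric(), config = NULL),
            class = "logit_ptic")
}

#' @export
print.logit_ptic <- function(x, ...) {
  cat(sprintf("logit PTIC: %d words, %s\n", ncol(x$W),
              if (length(x$trace)) sprintf("trained %d epochs (final loss %.6g)",
                                           length(x$trace),
                                           x$trace[length(x$trace)])
              else "untrained (W = 1)"))
  invisible(x)
}

#' Positive-class probability under a logit PTIC model
#'
#' Computes, per document, `z = sum over distinct in-vocabulary words of
#' tf-idf(w) * (assoc(pos, w) * W(pos, w) - assoc(neg, w) * W(neg, w))`
#' and returns `sigmoid(z)`. An empty document (no in-vocabulary words)
#' has `z = 0` and probability 0.5.
#'
#' @param model A [logit_ptic()] model.
#' @param corpus A [tokenized_corpus()].
#' @return Numeric vector of probabilities in (0, 1), named by `doc_id`.
#' @export
forward <- function(model, corpus) {
  stopifnot(inherits(model, "logit_ptic"))
  X <- tfidf_matrix(model$base, corpus)
  setNames(plogis(as.numeric(X %*% logit_weight_vector(model))),
           corpus$doc_id)
}

# the per-word linear weights a*Wpos - b*Wneg collapsed to one vector
logit_weight_vector <- function(model) {
  b <- model$base
  b$assoc[b$positive, ] * model$W[b$positive, ] -
    b$assoc[b$negative, ] * model$W[b$negative, ]
}

# mean loss and its gradient w.r.t. W on a (sub)set of documents.
# X: sparse tf-idf matrix; y: 1 for positive class, 0 otherwise.
logit_loss_grad <- function(W, X, y, assoc_pos, assoc_neg, loss, focal) {
  z <- as.numeric(X %*% (assoc_pos * W[1, ] - assoc_neg * W[2, ]))
  p <- plogis(z)
  eps <- 1e-12
  pc <- pmin(pmax(p, eps), 1 - eps)
  if (loss == "cross_entropy") {
    L <- -(y * log(pc) + (1 - y) * log(1 - pc))
    g <- p - y
  } else {
    pt <- ifelse(y == 1, pc, 1 - pc)
    at <- ifelse(y == 1, focal$alpha_pos, focal$alpha_neg)
    gam <- focal$gamma
    L <- -at * (1 - pt)^gam * log(pt)
    dLdpt <- if (gam == 0) {
      -at / pt
    } else {
      -at * (-gam * (1 - pt)^(gam - 1) * log(pt) + (1 - pt)^gam / pt)
    }
    g <- dLdpt * ifelse(y == 1, 1, -1) * p * (1 - p)
  }
  gz <- as.numeric(Matrix::crossprod(X, g)) / length(y)
  list(loss = mean(L),
       grad = rbind(assoc_pos * gz, -assoc_neg * gz))
}

#' Train a logit PTIC model by mini-batch gradient descent
#'
#' Optimizes the per-(class, word) weights with Adam on the chosen loss
#' (binary cross-entropy or focal loss), shuffling mini-batches each epoch
#' with the configured seed. Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]` inside the loss only, so `log(0)` cannot occur
#' during training. Training is deterministic given the seed.
#'
#' @param model A [logit_ptic()] model whose base was fitted on the same
#'   corpus (or one with compatible labels).
#' @param corpus Labeled [tokenized_corpus()].
#' @param config A [train_config()].
#' @return The trained `"logit_ptic"` model with the per-epoch mean loss
#'   in `$trace` and the config in `$config`.
#' @export
train_logit_ptic <- function(model, corpus, config = train_config()) {
  stopifnot(inherits(model, "logit_ptic"),
            inherits(config, "train_config"))
  b <- model$base
  if (is.null(corpus$label)) stop("training requires a labeled corpus")
  y <- as.numeric(corpus$label == b$positive)
  X <- tfidf_matrix(b, corpus)
  ap <- b$assoc[b$positive, ]
  an <- b$assoc[b$negative, ]
  W <- model$W
  ndoc <- length(y)

  set.seed(config$seed)
  m <- matrix(0, nrow(W), ncol(W))
  v <- matrix(0, nrow(W), ncol(W))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(ndoc)
    batch_losses <- c()
    for (start in seq(1, ndoc, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, ndoc)]
      lg <- logit_loss_grad(W, X[idx, , drop = FALSE], y[idx],
                            ap, an, config$loss, config$focal)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d (batch starting %d)",
                     epoch, start))
      }
      step <- step + 1L
      m <- beta1 * m + (1 - beta1) * lg$grad
      v <- beta2 * v + (1 - beta2) * lg$grad^2
      m_hat <- m / (1 - beta1^step)
      v_hat <- v / (1 - beta2^step)
      W <- W - config$learning_rate * m_hat / (sqrt(v_hat) + adam_eps)
      batch_losses <- c(batch_losses, lg$loss)
    }
    trace[epoch] <- mean(batch_losses)
  }
  model$W <- W
  model$trace <- trace
  model$config <- config
  model
}

#' @rdname classify
#' @param threshold Positive-decision cutoff in (0, 1) for logit PTIC
#'   (default 0.5, equivalent to the argmax rule); raising it trades
#'   recall for precision on imbalanced data.
#' @export
classify.logit_ptic <- function(model, corpus, threshold = 0.5, ...) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  p <- forward(model, corpus)
  b <- model$base
  data.frame(
    doc_id = corpus$doc_id,
    score_pos = p,
    score_neg = 1 - p,
    margin = p - threshold,
    predicted = ifelse(p >= threshold, b$positive, b$negative),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @export
predict.logit_ptic <- function(object, newdata, threshold = 0.5, ...) {
  classify.logit_ptic(object, newdata, threshold = threshold, ...)
}
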