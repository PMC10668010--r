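#' Serialize a fitted model to JSON
#'
#' Writes a versioned JSON schema containing every table the model needs
#' at prediction time (association/idf or conditional-probability tables,
#' priors, vocabulary, configuration) plus the stopword snapshot, with
#' full floating-point precision, so a reloaded model reproduces
#' predictions bit for bit.
#'
#' @param model A `"ptic_model"`, `"logit_ptic"` or `"nb_model"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- model_to_list(model)
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a model serialized by [write_model()]
#'
#' @param path Path to the JSON model file.
#' @return The model object, with its original class.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_from_list(obj)
}

SCHEMA_VERSION <- "1.0"

named_num <- function(x) as.list(setNames(as.numeric(x), names(x)))

model_to_list <- function(model) {
  if (inherits(model, "ptic_model")) {
    list(schema = SCHEMA_VERSION, type = "ptic",
         vocab = model$vocab, class_labels = model$class_labels,
         positive = model$positive, negative = model$negative,
         assoc = apply(model$assoc, 1, named_num, simplify = FALSE),
         idf = named_num(model$idf), priors = named_num(model$priors),
         association_mode = model$association_mode,
         probability_mode = model$probability_mode,
         summation = model$summation, min_count = model$min_count,
         N = model$N, N_word = named_num(model$N_word),
         total_word_count = named_num(model$total_word_count),
         stopwords = model$stopwords)
  } else if (inherits(model, "logit_ptic")) {
    list(schema = SCHEMA_VERSION, type = "logit_ptic",
         base = model_to_list(model$base),
         W = apply(model$W, 1, named_num, simplify = FALSE),
         trace = model$trace,
         config = if (is.null(model$config)) NULL else {
           cfg <- unclass(model$config)
           cfg$focal <- unclass(cfg$focal)
           cfg
         })
  } else if (inherits(model, "nb_model")) {
    list(schema = SCHEMA_VERSION, type = "naive_bayes",
         vocab = model$vocab, class_labels = model$class_labels,
         positive = model$positive, negative = model$negative,
         log_prior = named_num(model$log_prior),
         log_cond = apply(model$log_cond, 1, named_num, simplify = FALSE),
         alpha = model$alpha, min_count = model$min_count)
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
}

table_from_list <- function(rows, class_labels, vocab) {
  out <- do.call(rbind, lapply(class_labels, function(cl)
    unlist(rows[[cl]])[vocab]))
  dimnames(out) <- list(class_labels, vocab)
  out
}

model_from_list <- function(obj) {
  if (is.null(obj$type)) stop("not a pticlass model file")
  switch(obj$type,
    ptic = {
      vocab <- obj$vocab
      structure(list(
        vocab = vocab, class_labels = obj$class_labels,
        positive = obj$positive, negative = obj$negative,
        assoc = table_from_list(obj$assoc, obj$class_labels, vocab),
        idf = unlist(obj$idf)[vocab],
        priors = unlist(obj$priors)[obj$class_labels],
        association_mode = obj$association_mode,
        probability_mode = obj$probability_mode,
        summation = obj$summation, min_count = obj$min_count,
        N = obj$N, N_word = unlist(obj$N_word)[vocab],
        total_word_count = unlist(obj$total_word_count)[vocab],
        stopwords = obj$stopwords
      ), class = "ptic_model")
    },
    logit_ptic = {
      base <- model_from_list(obj$base)
      cfg <- obj$config
      if (!is.null(cfg)) {
        cfg$focal <- do.call(focal_params, as.list(cfg$focal))
        cfg <- do.call(train_config,
                       cfg[c("epochs", "batch_size", "learning_rate",
                             "loss", "focal", "seed")])
      }
      structure(list(
        base = base,
        W = table_from_list(obj$W, base$class_labels, base$vocab),
        trace = as.numeric(unlist(obj$trace)),
        config = cfg
      ), class = "logit_ptic")
    },
    naive_bayes = {
      vocab <- obj$vocab
      structure(list(
        class_labels = obj$class_labels, positive = obj$positive,
        negative = obj$negative,
        log_prior = unlist(obj$log_prior)[obj$class_labels],
        log_cond = table_from_list(obj$log_cond, obj$class_labels, vocab),
        alpha = obj$alpha, min_count = obj$min_count, vocab = vocab
      ), class = "nb_model")
    },
    stop("unknown model type: ", obj$type)
  )
}

#' Write predictions to a delimited file
#'
#' @param predictions Prediction data frame from [classify()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
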