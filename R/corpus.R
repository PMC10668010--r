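#' English stopword list shipped with the package
#'
#' A fixed English stopword snapshot vendored into the package (one word per
#' line under `inst/extdata/stopwords_en.txt`). A snapshot, rather than a
#' list pulled from an external library at run time, keeps tokenization --
#' and therefore every fitted model -- reproducible across installations.
#' The list used to fit a model is serialized with the model.
#'
#' @return Character vector of lowercase stopwords.
#' @export
#' @examples
#' head(ptic_stopwords())
ptic_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "pticlass")
  readLines(path, encoding = "UTF-8")
}

#' Tokenize free text into lowercase alphabetic words
#'
#' Splits on any non-alphabetic character (so hyphenated compounds such as
#' "drug-induced" become two tokens), lowercases, keeps only tokens matching
#' `^[a-z]+$`, and removes stopwords. Token order is preserved. Non-ASCII
#' letters are excluded by the alphabetic filter (documented limitation).
#'
#' @param text Character vector of texts (may be empty strings).
#' @param stopwords Character vector of words to drop
#'   (default [ptic_stopwords()]).
#' @return For a single input string, a character vector of tokens; for a
#'   vector input, a list of token vectors.
#' @export
#' @examples
#' tokenize("The Drug-induced LIVER injury.")
tokenize <- function(text, stopwords = ptic_stopwords()) {
  stopifnot(is.character(text))
  out <- lapply(strsplit(tolower(text), "[^a-z]+"), function(tok) {
    tok <- tok[nzchar(tok)]
    tok[!tok %in% stopwords]
  })
  if (length(text) == 1L) out[[1L]] else out
}

#' Construct a tokenized corpus
#'
#' Bundles per-document token vectors with document ids and (optional)
#' binary class labels. This is the in-memory form every fitting and
#' prediction function consumes.
#'
#' @param tokens List of character vectors, one per document.
#' @param doc_id Character vector of unique document ids.
#' @param label Optional character vector of class tags (`NULL` for an
#'   unlabeled corpus).
#' @return An object of class `"tokenized_corpus"`: a list with elements
#'   `doc_id`, `tokens`, `label` and `n` (token count per document).
#' @export
tokenized_corpus <- function(tokens, doc_id = NULL, label = NULL) {
  stopifnot(is.list(tokens))
  if (is.null(doc_id)) doc_id <- sprintf("doc%06d", seq_along(tokens))
  doc_id <- as.character(doc_id)
  if (anyDuplicated(doc_id)) stop("doc_id values must be unique")
  if (length(doc_id) != length(tokens)) {
    stop("doc_id and tokens must have the same length")
  }
  if (!is.null(label)) {
    label <- as.character(label)
    if (length(label) != length(tokens)) {
      stop("label and tokens must have the same length")
    }
  }
  structure(
    list(doc_id = doc_id, tokens = tokens, label = label,
         n = lengths(tokens)),
    class = "tokenized_corpus"
  )
}

#' @export
print.tokenized_corpus <- function(x, ...) {
  cat(sprintf("Tokenized corpus: %d documents, %s\n", length(x$tokens),
              if (is.null(x$label)) "unlabeled"
              else paste(sprintf("%s=%d", names(table(x$label)),
                                 table(x$label)), collapse = ", ")))
  invisible(x)
}

#' @export
length.tokenized_corpus <- function(x) length(x$tokens)

#' @export
`[.tokenized_corpus` <- function(x, i) {
  tokenized_corpus(x$tokens[i], x$doc_id[i],
                   if (is.null(x$label)) NULL else x$label[i])
}

#' Tokenize a corpus data frame
#'
#' Concatenates title and abstract with a single separator space, then
#' applies [tokenize()] to each document.
#'
#' @param corpus Data frame with columns `doc_id`, `title`, `abstract` and
#'   optionally `label` (as returned by [read_corpus()] or
#'   [generate_corpus()]).
#' @param stopwords Stopword list (default [ptic_stopwords()]).
#' @return A [tokenized_corpus()].
#' @export
tokenize_corpus <- function(corpus, stopwords = ptic_stopwords()) {
  need <- c("doc_id", "title", "abstract")
  miss <- setdiff(need, names(corpus))
  if (length(miss)) stop("corpus is missing column(s): ",
                         paste(miss, collapse = ", "))
  text <- paste(corpus$title, corpus$abstract)
  toks <- lapply(strsplit(tolower(text), "[^a-z]+"), function(tok) {
    tok <- tok[nzchar(tok)]
    tok[!tok %in% stopwords]
  })
  tokenized_corpus(toks, corpus$doc_id,
                   if ("label" %in% names(corpus)) corpus$label else NULL)
}

#' Build the restricted vocabulary
#'
#' Retains exactly the words whose total occurrence count (token count,
#' summed over the whole corpus) is at least `min_count`. The default of 5
#' is the model's standard minimum-occurrence threshold.
#'
#' @param corpus A [tokenized_corpus()] or a plain list of token vectors.
#' @param min_count Integer >= 1; minimum total corpus occurrence count.
#' @return Sorted character vector of retained words.
#' @export
build_vocabulary <- function(corpus, min_count = 5) {
  stopifnot(min_count >= 1)
  tokens <- if (inherits(corpus, "tokenized_corpus")) corpus$tokens else corpus
  all_tok <- unlist(tokens, use.names = FALSE)
  if (length(all_tok) == 0) return(character())
  tab <- table(all_tok)
  sort(names(tab)[tab >= min_count])
}

#' Document/class/word occurrence counts
#'
#' Tabulates everything the probabilistic machinery derives from: document
#' counts per class, document frequencies, class-conditional document
#' frequencies, within-document term counts (as a sparse document-term
#' matrix), and token-level totals. Words outside `vocab` are ignored in
#' the tables but still contribute to each document's total token count
#' `doc_n` (the `n` in the tf factor 1/n).
#'
#' @param corpus Labeled [tokenized_corpus()]; every document must carry a
#'   non-missing label.
#' @param vocab Non-empty character vector of retained words.
#' @return An object of class `"ptic_counts"` with elements `N`, `classes`,
#'   `N_class`, `N_word`, `N_class_word` (class x word matrix),
#'   `total_word_count`, `tokens_per_class`, `token_class_word`, `dtm`
#'   (sparse document x word term-count matrix), `doc_n`, `doc_id`,
#'   `labels`.
#' @export
count_table <- function(corpus, vocab) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  if (length(vocab) == 0) stop("vocab must be non-empty")
  lab <- corpus$label
  if (is.null(lab)) stop("count_table() requires a labeled corpus")
  bad <- is.na(lab) | !nzchar(lab)
  if (any(bad)) {
    stop("document(s) with unknown label tag: ",
         paste(corpus$doc_id[bad], collapse = ", "))
  }
  classes <- sort(unique(lab))
  dtm <- dtm_from_tokens(corpus$tokens, vocab)
  present <- dtm
  present@x[] <- 1
  N_class_word <- matrix(0, length(classes), length(vocab),
                         dimnames = list(classes, vocab))
  token_class_word <- N_class_word
  for (cl in classes) {
    rows <- lab == cl
    N_class_word[cl, ] <- Matrix::colSums(present[rows, , drop = FALSE])
    token_class_word[cl, ] <- Matrix::colSums(dtm[rows, , drop = FALSE])
  }
  structure(
    list(
      N = length(corpus$tokens),
      classes = classes,
      N_class = setNames(as.integer(table(factor(lab, classes))), classes),
      N_word = setNames(as.integer(Matrix::colSums(present)), vocab),
      N_class_word = N_class_word,
      total_word_count = setNames(as.integer(Matrix::colSums(dtm)), vocab),
      tokens_per_class = rowSums(token_class_word),
      token_class_word = token_class_word,
      dtm = dtm,
      doc_n = corpus$n,
      doc_id = corpus$doc_id,
      labels = lab,
      vocab = vocab
    ),
    class = "ptic_counts"
  )
}

# sparse document x word term-count matrix; duplicated (i,j) pairs are summed
dtm_from_tokens <- function(tokens, vocab) {
  all_tok <- unlist(tokens, use.names = FALSE)
  i <- rep.int(seq_along(tokens), lengths(tokens))
  j <- match(all_tok, vocab)
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                       dims = c(length(tokens), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Read a delimited corpus file
#'
#' Expects a header with columns `id`, `title`, `abstract` and optionally
#' `label` (any column order; extra columns are ignored). The reader is
#' deliberately strict: rows whose field count does not match the header
#' are reported with their line numbers. Fields must not contain the
#' separator; [write_corpus()] guarantees this on output.
#'
#' @param path Path to the file.
#' @param sep Field separator: `"\t"` (default) or `","`.
#' @return Data frame with columns `doc_id`, `title`, `abstract` and, when
#'   present in the file, `label`.
#' @export
read_corpus <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty corpus file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  need <- c("id", "title", "abstract")
  miss <- setdiff(need, header)
  if (length(miss)) {
    stop("corpus file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  body <- fields[-1L]
  # trailing empty fields (e.g. an empty abstract before end-of-line) are
  # dropped by strsplit; pad them back
  nf <- lengths(body)
  short <- nf < length(header) & nf >= length(header) - 1L
  body[short] <- lapply(body[short], function(f)
    c(f, rep("", length(header) - length(f))))
  bad <- which(lengths(body) != length(header))
  if (length(bad)) {
    stop("malformed corpus row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  }
  mat <- do.call(rbind, body)
  colnames(mat) <- header
  out <- data.frame(
    doc_id = mat[, "id"],
    title = mat[, "title"],
    abstract = mat[, "abstract"],
    stringsAsFactors = FALSE
  )
  if ("label" %in% header) out$label <- mat[, "label"]
  out
}

#' Write a corpus to a delimited text file
#'
#' Inverse of [read_corpus()]. Separator and newline characters inside text
#' fields are replaced by single spaces so that the file round-trips.
#'
#' @param corpus Data frame with `doc_id`, `title`, `abstract`, optional
#'   `label`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, sep = "\t") {
  clean <- function(x) gsub(paste0("[", sep, "\r\n]+"), " ", x)
  cols <- c("id", "title", "abstract")
  rows <- paste(clean(corpus$doc_id), clean(corpus$title),
                clean(corpus$abstract), sep = sep)
  if ("label" %in% names(corpus)) {
    cols <- c(cols, "label")
    rows <- paste(rows, clean(corpus$label), sep = sep)
  }
  writeLines(c(paste(cols, collapse = sep), rows), path, useBytes = TRUE)
  invisible(path)
}
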