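#' Tokenize a record's title and abstract
#'
#' The text fed to every vectorizer is the concatenation of title and
#' abstract, lowercased, with punctuation stripped, split on whitespace,
#' and tokens shorter than 2 characters dropped. Idempotent on its own
#' output.
#'
#' @param title,abstract character scalars (abstract may be empty).
#' @return character vector of tokens (possibly empty, with a warning when
#'   a record yields no tokens).
#' @export
preprocess_text <- function(title, abstract = "") {
  txt <- paste(title, abstract)
  txt <- stringi::stri_trans_tolower(txt)
  txt <- gsub("[^[:alnum:][:space:]]+", " ", txt)
  tokens <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
  tokens <- tokens[nchar(tokens) >= 2]
  if (length(tokens) == 0) {
    warning("record yields an empty token sequence", call. = FALSE)
  }
  tokens
}

# Token sequences for every record of a corpus, as a named list.
tokenize_corpus <- function(corpus) {
  out <- lapply(seq_len(nrow(corpus)), function(i) {
    suppressWarnings(preprocess_text(corpus$title[i], corpus$abstract[i]))
  })
  names(out) <- corpus$record_id
  out
}

#' Fit a per-collection vectorizer
#'
#' Embeds every record of a corpus as one numeric vector. Two methods sit
#' behind the same contract (a matrix with one row per `record_id`):
#'
#' * `"tfidf"` — term frequency times smoothed inverse document frequency
#'   (`idf = log((1 + N)/(1 + df)) + 1`), L2-normalized rows, sublinear tf
#'   off. Fully deterministic; the dimension is the vocabulary size.
#'   The reference ranker for tests and a strong baseline.
#' * `"paragraph"` — distributed bag-of-words paragraph vectors trained by
#'   stochastic gradient descent with negative sampling, the embedding
#'   family the ranking method was designed around. Training is
#'   single-threaded with an internal RNG, so a fixed `train_seed`
#'   reproduces vectors bit-for-bit. Words occurring fewer than
#'   `min_count` times are dropped; a record whose tokens all fall below
#'   `min_count` receives the zero vector and so ranks last.
#'
#' @param corpus a corpus with at least 2 records carrying non-empty
#'   token sequences.
#' @param method `"tfidf"` or `"paragraph"`.
#' @param dimension paragraph-vector length (default 100; ignored for
#'   tf-idf, whose dimension is the vocabulary size).
#' @param epochs training passes over the corpus (paragraph; default 40).
#' @param min_count minimum corpus frequency for a word to enter the
#'   paragraph-vector vocabulary (default 2).
#' @param negative number of negative samples per target word (default 5).
#' @param alpha,min_alpha initial and final SGD learning rate.
#' @param train_seed integer seed for reproducible paragraph training.
#' @return a `vector_model`: list with `method`, `dimension`, `vectors`
#'   (matrix, rownames = record ids), `train_seed`, `trained_on` (corpus
#'   fingerprint), `vocabulary` and `config`.
#' @export
fit_vectorizer <- function(corpus, method = c("tfidf", "paragraph"),
                           dimension = 100, epochs = 40, min_count = 2,
                           negative = 5, alpha = 0.025, min_alpha = 1e-4,
                           train_seed = 1L) {
  method <- match.arg(method)
  tokens <- tokenize_corpus(corpus)
  nonempty <- sum(lengths(tokens) > 0)
  if (nrow(corpus) < 2 || nonempty < 2) {
    stop_data("vectorizer training needs at least 2 records with non-empty text (got %d)",
              nonempty)
  }
  vectors <- switch(method,
    tfidf = tfidf_vectors(tokens),
    paragraph = paragraph_vectors(tokens, dimension, epochs, min_count,
                                  negative, alpha, min_alpha, train_seed)
  )
  structure(
    list(
      method = method,
      dimension = ncol(vectors),
      vectors = vectors,
      train_seed = as.integer(train_seed),
      trained_on = corpus_fingerprint(corpus),
      vocabulary = colnames(vectors) %||% attr(vectors, "vocabulary"),
      config = list(dimension = dimension, epochs = epochs, min_count = min_count,
                    negative = negative, alpha = alpha, min_alpha = min_alpha)
    ),
    class = "vector_model"
  )
}

tfidf_vectors <- function(tokens) {
  vocab <- sort(unique(unlist(tokens, use.names = FALSE)))
  n_docs <- length(tokens)
  counts <- lapply(tokens, function(tk) table(factor(tk, levels = vocab)))
  i <- rep(seq_len(n_docs), vapply(counts, function(ct) sum(ct > 0), 0L))
  j <- unlist(lapply(counts, function(ct) which(ct > 0)), use.names = FALSE)
  x <- unlist(lapply(counts, function(ct) as.numeric(ct[ct > 0])), use.names = FALSE)
  tf <- Matrix::sparseMatrix(i = i, j = j, x = x,
                             dims = c(n_docs, length(vocab)),
                             dimnames = list(names(tokens), vocab))
  df <- Matrix::colSums(tf > 0)
  idf <- log((1 + n_docs) / (1 + df)) + 1
  m <- tf %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  m <- Matrix::Diagonal(x = 1 / norms) %*% m
  dimnames(m) <- list(names(tokens), vocab)
  m
}

paragraph_vectors <- function(tokens, dimension, epochs, min_count,
                              negative, alpha, min_alpha, train_seed) {
  counts <- table(unlist(tokens, use.names = FALSE))
  vocab <- sort(names(counts)[counts >= min_count])
  if (length(vocab) == 0) {
    stop_data("paragraph vocabulary is empty: every token falls below min_count = %d",
              min_count)
  }
  docs <- lapply(tokens, function(tk) {
    ids <- match(tk, vocab)
    as.integer(ids[!is.na(ids)] - 1L)
  })
  freq <- as.numeric(counts[vocab])^0.75
  cdf <- cumsum(freq / sum(freq))
  cdf[length(cdf)] <- 1
  m <- pvdbow_train(docs, length(vocab), as.integer(dimension),
                    as.integer(epochs), alpha, min_alpha,
                    as.integer(negative), cdf, as.integer(train_seed))
  # all-OOV records get the zero vector so they rank last
  m[lengths(docs) == 0, ] <- 0
  rownames(m) <- names(tokens)
  attr(m, "vocabulary") <- vocab
  m
}

#' @export
print.vector_model <- function(x, ...) {
  cat(sprintf("<vector_model> method=%s, %d record(s) x %d dim, seed=%d\n",
              x$method, nrow(x$vectors), x$dimension, x$train_seed))
  invisible(x)
}

model_vectors <- function(model, ids = NULL) {
  v <- model$vectors
  if (is.null(ids)) v else v[ids, , drop = FALSE]
}

#' Cosine similarity between two vectors
#'
#' Symmetric, in `[-1, 1]`; a zero vector scores 0 against anything (by
#' convention, so out-of-vocabulary records rank last rather than
#' producing NaN).
#'
#' @param a,b numeric vectors of equal length.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop_contract("dimension mismatch: %d vs %d", length(a), length(b))
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Cosine similarity of every row of `cand` against every row of `ref`
# (dense or sparse), as a |cand| x |ref| matrix; zero rows score 0.
cosine_matrix <- function(cand, ref) {
  rn <- function(m) {
    nrm <- sqrt(Matrix::rowSums(m^2))
    nrm[nrm == 0] <- 1
    as.matrix(Matrix::Diagonal(x = 1 / nrm) %*% m)
  }
  out <- rn(cand) %*% t(rn(ref))
  dimnames(out) <- list(rownames(cand), rownames(ref))
  out
}
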