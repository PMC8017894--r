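# Fixtures and independent oracles. The oracles recompute tf-idf, cosine
# similarity and the ranked screening order from their definitions with
# plain loops, so they share no code with the implementation paths they
# check.

make_corpus <- function(titles, abstracts = rep("", length(titles)),
                        ids = sprintf("R%03d", seq_along(titles))) {
  new_corpus(tibble::tibble(record_id = ids, title = titles, abstract = abstracts))
}

write_ris_fixture <- function(path, entries) {
  lines <- unlist(lapply(entries, function(e) {
    c("TY  - JOUR",
      paste0("TI  - ", e$title),
      if (!is.null(e$abstract)) paste0("AB  - ", e$abstract),
      vapply(e$authors %||% character(0), function(a) paste0("AU  - ", a), ""),
      if (!is.null(e$year)) paste0("PY  - ", e$year),
      if (!is.null(e$doi)) paste0("DO  - ", e$doi),
      "ER  - ", "")
  }))
  writeLines(lines, path, useBytes = TRUE)
  path
}

# --- independent oracles -------------------------------------------------

oracle_tokens <- function(corpus) {
  lapply(seq_len(nrow(corpus)), function(i) {
    txt <- tolower(paste(corpus$title[i], corpus$abstract[i]))
    txt <- gsub("[^a-z0-9 ]+", " ", txt)
    tk <- strsplit(trimws(txt), " +")[[1]]
    tk[nchar(tk) >= 2]
  }) |> stats::setNames(corpus$record_id)
}

oracle_tfidf <- function(token_list) {
  vocab <- sort(unique(unlist(token_list)))
  n <- length(token_list)
  tf <- matrix(0, n, length(vocab),
               dimnames = list(names(token_list), vocab))
  for (i in seq_len(n)) {
    for (tk in token_list[[i]]) tf[i, tk] <- tf[i, tk] + 1
  }
  df <- colSums(tf > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  m <- sweep(tf, 2, idf, `*`)
  for (i in seq_len(n)) {
    nrm <- sqrt(sum(m[i, ]^2))
    if (nrm > 0) m[i, ] <- m[i, ] / nrm
  }
  m
}

oracle_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Max-cosine score of every pool member against the relevant exemplars.
oracle_scores <- function(vectors, pool, relevant) {
  vapply(pool, function(u) {
    max(vapply(relevant, function(r) oracle_cosine(vectors[u, ], vectors[r, ]), 0))
  }, 0)
}

# Brute-force sort-and-step replay: rank the unscreened pool by
# max-cosine to seeds+flags, present batches of `round_size`, fold the
# batch's flagged members into the relevant set at the round boundary.
# Returns the full presentation order and the decision index at which the
# last final article (outside the seeds) is screened.
oracle_replay <- function(corpus, seeds, flagged, final, round_size = 50) {
  tokens <- oracle_tokens(corpus)
  vectors <- oracle_tfidf(tokens)
  pool <- setdiff(corpus$record_id, seeds)
  relevant <- seeds
  order_out <- character(0)
  while (length(pool) > 0) {
    sc <- oracle_scores(vectors, pool, relevant)
    batch <- pool[order(-sc, pool)][seq_len(min(round_size, length(pool)))]
    order_out <- c(order_out, batch)
    relevant <- union(relevant, intersect(batch, flagged))
    pool <- setdiff(pool, batch)
  }
  targets <- setdiff(final, seeds)
  stop_at <- if (length(targets) == 0) 0L else max(match(targets, order_out))
  list(order = order_out, n_reviewed_at_last_final = stop_at)
}

# Expected fraction of a pool screened to find all m relevant records
# under a uniformly random presentation order: E[max position] = m(P+1)/(m+1).
random_order_expected_fraction <- function(m, pool_size) {
  m * (pool_size + 1) / ((m + 1) * pool_size)
}
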