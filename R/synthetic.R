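#' Specification for a synthetic labelled corpus
#'
#' Describes a pseudo-text search result with a controllable topical
#' signal: `n_total` records whose tokens are drawn from a shared
#' Zipf-distributed vocabulary (realistic inverse-document-frequency
#' structure), of which `n_flagged` relevant records additionally draw a
#' fraction `topic_injection_rate` of their tokens from a topic block
#' exclusive to relevant records; decoys never touch the topic block.
#' `n_final` of the flagged records form the final-inclusion target set.
#' Token "words" are synthetic identifiers, not natural language — enough
#' structure for both vectorizer methods, nothing more.
#'
#' @param n_total corpus size (default 500).
#' @param n_flagged relevant records (default 15).
#' @param n_final final inclusions, a random subset of the flagged
#'   (default 6).
#' @param vocab_size shared vocabulary size (default 2000).
#' @param topic_block_size tokens exclusive to relevant records
#'   (default 50).
#' @param topic_injection_rate fraction of a relevant record's tokens
#'   drawn from the topic block, in `[0, 1]` (default 0.5; 0 gives an
#'   unlearnable null corpus for sanity checks).
#' @param abstract_length mean abstract length in tokens (Poisson, floored
#'   at 30; default 120). Titles are 8 tokens.
#' @param n_duplicates byte-exact duplicate records to append (default 0).
#' @param rng_seed integer seed; generation is fully deterministic.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_total = 500, n_flagged = 15, n_final = 6,
                           vocab_size = 2000, topic_block_size = 50,
                           topic_injection_rate = 0.5, abstract_length = 120,
                           n_duplicates = 0, rng_seed = 1L) {
  spec <- list(n_total = as.integer(n_total), n_flagged = as.integer(n_flagged),
               n_final = as.integer(n_final), vocab_size = as.integer(vocab_size),
               topic_block_size = as.integer(topic_block_size),
               topic_injection_rate = topic_injection_rate,
               abstract_length = abstract_length,
               n_duplicates = as.integer(n_duplicates),
               rng_seed = as.integer(rng_seed))
  if (spec$n_final > spec$n_flagged || spec$n_flagged > spec$n_total) {
    stop_usage("need n_final <= n_flagged <= n_total")
  }
  if (spec$n_final < 0 || spec$vocab_size < 1 || spec$topic_block_size < 1) {
    stop_usage("counts must be positive")
  }
  if (topic_injection_rate < 0 || topic_injection_rate > 1) {
    stop_usage("topic_injection_rate must lie in [0, 1]")
  }
  if (abstract_length <= 0) stop_usage("abstract_length must be positive")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic labelled corpus
#'
#' Builds the corpus described by a [synthetic_spec()]: decoy records
#' sample all tokens from the shared Zipf vocabulary; flagged records
#' sample each token from the exclusive topic block with probability
#' `topic_injection_rate` and from the shared vocabulary otherwise.
#' Deterministic under `rng_seed` (same spec, same seed, identical
#' corpus). Flagged and final sets are random subsets of the required
#' sizes with `final` nested in `flagged`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [labelled_corpus()].
#' @export
generate_corpus <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  with_private_seed(spec$rng_seed, {
    shared <- sprintf("w%05d", seq_len(spec$vocab_size))
    zipf_p <- (1 / seq_len(spec$vocab_size))
    zipf_p <- zipf_p / sum(zipf_p)
    topic <- sprintf("topicterm%04d", seq_len(spec$topic_block_size))

    ids <- sprintf("SYN%05d", seq_len(spec$n_total))
    flagged <- sort(sample(ids, spec$n_flagged))
    final <- sort(sample(flagged, spec$n_final))

    draw_tokens <- function(n, relevant) {
      from_topic <- relevant & runif(n) < spec$topic_injection_rate
      out <- character(n)
      if (any(from_topic)) out[from_topic] <- sample(topic, sum(from_topic), replace = TRUE)
      if (any(!from_topic)) {
        out[!from_topic] <- sample(shared, sum(!from_topic), replace = TRUE, prob = zipf_p)
      }
      out
    }

    records <- lapply(seq_len(spec$n_total), function(i) {
      relevant <- ids[i] %in% flagged
      len <- max(30L, rpois(1, spec$abstract_length))
      title <- paste(draw_tokens(8L, relevant), collapse = " ")
      abstract <- paste(draw_tokens(len, relevant), collapse = " ")
      tibble::tibble(record_id = ids[i], title = title, abstract = abstract,
                     year = sample(1990:2025, 1))
    })
    corpus <- new_corpus(do.call(rbind, records), source_file = "synthetic")
    if (spec$n_duplicates > 0) {
      corpus <- inject_duplicates(corpus, spec$n_duplicates,
                                  rng_seed = spec$rng_seed + 1L)
    }
    labelled_corpus(corpus, flagged, final)
  })
}

#' Inject duplicate records into a corpus
#'
#' Appends `n` copies of randomly chosen records under fresh record ids,
#' to exercise de-duplication. Exact copies are byte-identical in title
#' and abstract (removed by strict mode); with `perturb = TRUE` the
#' copies get a trailing space and an uppercased title — surviving strict
#' matching but caught by normalized mode, by construction.
#'
#' @param corpus a corpus.
#' @param n number of duplicates to append (`n <= n_total(corpus)`).
#' @param rng_seed seed for choosing which records to copy.
#' @param perturb whitespace/case-perturb the copies instead of exact
#'   duplication.
#' @return the corpus with `n` extra records appended.
#' @export
inject_duplicates <- function(corpus, n, rng_seed = 1L, perturb = FALSE) {
  n <- as.integer(n)
  if (n < 0 || n > nrow(corpus)) {
    stop_contract("n must lie in [0, %d]", nrow(corpus))
  }
  if (n == 0) return(corpus)
  with_private_seed(rng_seed, {
    idx <- sample(nrow(corpus), n)
    copies <- corpus[idx, , drop = FALSE]
    copies$record_id <- paste0(copies$record_id, "-dup", seq_len(n))
    if (perturb) {
      copies$title <- paste0(stringi::stri_trans_toupper(copies$title), " ")
    }
    out <- rbind(corpus, copies)
    class(out) <- class(corpus)
    out
  })
}
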