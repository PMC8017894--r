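#' Start a screening session
#'
#' Initializes the seed-driven screening loop over a corpus: seed
#' articles are known-relevant exemplars supplied up front; they are
#' treated as implicit inclusions, are never presented for screening, and
#' anchor the relevance ranking. Articles are then presented in rounds of
#' `round_size` (default 50), re-ranked between rounds as reviewers flag
#' further relevant articles.
#'
#' @param corpus a [new_corpus()] object.
#' @param model a [fit_vectorizer()] model trained on the same corpus.
#' @param seed_ids non-empty character vector of record ids present in
#'   the corpus.
#' @param round_size articles per round (default 50).
#' @param halt_threshold optional fraction in `(0, 1]` of the screenable
#'   pool; once that fraction has been decided the loop reports a halt
#'   (the pre-agreed evidence-based stopping point). `NULL` means screen
#'   to exhaustion.
#' @param aggregation how a candidate's similarities to the relevant
#'   exemplars are combined into one score: `"max"` (default; preserves
#'   multi-topic seed sets) or `"mean"`.
#' @param dedup_report optional `duplicate_report` to attach for export.
#' @return a `screening_session` object.
#' @export
init_session <- function(corpus, model, seed_ids, round_size = 50,
                         halt_threshold = NULL,
                         aggregation = c("max", "mean"),
                         dedup_report = NULL) {
  aggregation <- match.arg(aggregation)
  if (length(seed_ids) == 0) {
    stop_usage("at least 1 seed article is required")
  }
  missing <- setdiff(seed_ids, corpus$record_id)
  if (length(missing) > 0) {
    stop_data("seed id(s) not in corpus: %s", paste(missing, collapse = ", "))
  }
  if (!is.numeric(round_size) || round_size < 1) {
    stop_usage("round_size must be a positive integer")
  }
  if (!is.null(halt_threshold) &&
      (!is.numeric(halt_threshold) || halt_threshold <= 0 || halt_threshold > 1)) {
    stop_usage("halt_threshold must lie in (0, 1]")
  }
  fp <- corpus_fingerprint(corpus)
  if (!identical(model$trained_on, fp)) {
    warning("vector model fingerprint does not match the corpus", call. = FALSE)
  }
  structure(
    list(
      corpus = corpus,
      corpus_ref = fp,
      model = model,
      seed_ids = unique(as.character(seed_ids)),
      round_size = as.integer(round_size),
      halt_threshold = halt_threshold,
      aggregation = aggregation,
      round_index = 0L,
      decisions = tibble::tibble(reviewer = character(0), record_id = character(0),
                                 decision = character(0), flag = logical(0),
                                 round = integer(0), timestamp = character(0)),
      flags = character(0),
      presented = tibble::tibble(round = integer(0), record_id = character(0)),
      current_round = NULL,
      dedup_report = dedup_report
    ),
    class = "screening_session"
  )
}

#' @export
print.screening_session <- function(x, ...) {
  cat(sprintf(
    "<screening_session> %d record(s), %d seed(s), round size %d, %d completed round(s), %d decision(s), %d flag(s)\n",
    nrow(x$corpus), length(x$seed_ids), x$round_size, x$round_index,
    nrow(x$decisions), length(x$flags)))
  invisible(x)
}

# Record ids eligible for presentation: not a seed, never presented.
screenable_ids <- function(session) {
  setdiff(session$corpus$record_id, c(session$seed_ids, session$presented$record_id))
}

# Size of the screenable pool at session start (everything but seeds).
pool_size <- function(session) {
  nrow(session$corpus) - length(session$seed_ids)
}

#' Relevance scores for unscreened records
#'
#' Each unscreened candidate is scored by its similarity to the relevant
#' set — the seed articles plus every article flagged so far. With the
#' default `"max"` aggregation, `score(u) = max_r cosine(v_u, v_r)`.
#' Excluded articles simply leave the pool; they contribute no signal.
#' Deterministic given the model.
#'
#' @param session a screening session.
#' @return named numeric vector of scores over the unscreened records,
#'   unsorted.
#' @export
relevance_scores <- function(session) {
  cand <- screenable_ids(session)
  if (length(cand) == 0) return(stats::setNames(numeric(0), character(0)))
  relevant <- unique(c(session$seed_ids, session$flags))
  sims <- cosine_matrix(model_vectors(session$model, cand),
                        model_vectors(session$model, relevant))
  agg <- if (session$aggregation == "max") {
    apply(sims, 1, max)
  } else {
    rowMeans(sims)
  }
  stats::setNames(as.numeric(agg), cand)
}

#' Present the next round of top-ranked articles
#'
#' Takes the `round_size` highest-scoring unscreened records (ties broken
#' by ascending record id so rounds are bit-reproducible), logs them as
#' presented, and stores the batch as the session's current round. The
#' final round may be shorter. Ranking is refreshed only here, at round
#' boundaries — never within a round.
#'
#' @param session a screening session.
#' @return the updated session; `NULL` if the pool is exhausted (a halt
#'   signal, not an error). Access the batch with [current_round()].
#' @export
next_round <- function(session) {
  scores <- relevance_scores(session)
  if (length(scores) == 0) return(NULL)
  ord <- order(-scores, names(scores))
  take <- utils::head(ord, session$round_size)
  round_no <- session$round_index + 1L
  items <- tibble::tibble(record_id = names(scores)[take],
                          score = as.numeric(scores[take]))
  session$presented <- rbind(session$presented,
                             tibble::tibble(round = round_no, record_id = items$record_id))
  session$current_round <- structure(
    list(round = round_no, items = items), class = "ranked_round")
  session
}

#' @rdname next_round
#' @export
current_round <- function(session) session$current_round

#' @export
print.ranked_round <- function(x, ...) {
  cat(sprintf("<ranked_round> round %d, %d article(s)\n", x$round, nrow(x$items)))
  invisible(x)
}

#' Record a reviewer's decision on a presented article
#'
#' A record must have been presented before it can be decided, and each
#' reviewer may decide it only once. Flagging marks the article as
#' relevant for the next re-ranking and is only allowed together with an
#' include decision. The session's round counter advances when every
#' record of the current round has at least one decision.
#'
#' @param session a screening session.
#' @param reviewer reviewer identifier.
#' @param record_id the presented record being decided.
#' @param decision `"include"` or `"exclude"`.
#' @param flag mark the article relevant (feeds the next re-ranking);
#'   requires `decision = "include"`.
#' @return the updated session.
#' @export
record_decision <- function(session, reviewer, record_id,
                            decision = c("include", "exclude"), flag = FALSE) {
  decision <- match.arg(decision)
  if (flag && decision != "include") {
    stop_usage("flag = TRUE requires decision = 'include'")
  }
  if (!record_id %in% session$presented$record_id) {
    stop_usage("record '%s' has not been presented; decisions must follow presentation",
               record_id)
  }
  already <- session$decisions$reviewer == reviewer &
    session$decisions$record_id == record_id
  if (any(already)) {
    stop_usage("reviewer '%s' has already decided record '%s'", reviewer, record_id)
  }
  rnd <- session$presented$round[match(record_id, session$presented$record_id)]
  session$decisions <- rbind(session$decisions, tibble::tibble(
    reviewer = as.character(reviewer), record_id = as.character(record_id),
    decision = decision, flag = flag, round = rnd,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  ))
  if (flag) session$flags <- unique(c(session$flags, record_id))
  refresh_round_index(session)
}

# Internal bulk path used by the simulation replay and the CLI: decides
# every record of the current round in presentation order in one append.
decide_round <- function(session, reviewer, include_ids, flag_ids = include_ids) {
  rnd <- session$current_round
  if (is.null(rnd)) stop_usage("no current round to decide")
  ids <- rnd$items$record_id
  inc <- ids %in% include_ids
  flg <- ids %in% flag_ids & inc
  session$decisions <- rbind(session$decisions, tibble::tibble(
    reviewer = as.character(reviewer), record_id = ids,
    decision = ifelse(inc, "include", "exclude"), flag = flg,
    round = rnd$round, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  ))
  session$flags <- unique(c(session$flags, ids[flg]))
  refresh_round_index(session)
}

refresh_round_index <- function(session) {
  decided <- unique(session$decisions$record_id)
  complete <- vapply(split(session$presented$record_id, session$presented$round),
                     function(ids) all(ids %in% decided), TRUE)
  session$round_index <- sum(complete)
  session
}

#' Check the halting conditions
#'
#' The loop halts when every screenable article has been decided, or —
#' if a halt threshold was agreed — when the decided fraction of the
#' screenable pool reaches it. For example, a team with a pool of 3600
#' articles and a 50% threshold stops after 36 rounds of 50.
#'
#' @param session a screening session.
#' @return list with `status` (`"continue"` or `"halt"`) and `reason`
#'   (`NULL`, `"all_screened"` or `"threshold_reached"`).
#' @export
halt_check <- function(session) {
  n_decided <- length(unique(session$decisions$record_id))
  pool <- pool_size(session)
  if (n_decided >= pool) {
    return(list(status = "halt", reason = "all_screened"))
  }
  if (!is.null(session$halt_threshold) && pool > 0 &&
      n_decided / pool >= session$halt_threshold) {
    return(list(status = "halt", reason = "threshold_reached"))
  }
  list(status = "continue", reason = NULL)
}

#' Identify conflicting decisions between reviewers
#'
#' A conflict is a record that received non-unanimous include/exclude
#' decisions from two or more reviewers who each screened it. Records
#' decided by a single reviewer are not conflicts.
#'
#' @param session a session with decisions from at least 2 reviewers.
#' @return a `conflict_set`: list with `conflicts` (tibble of
#'   `record_id`, `reviewer`, `decision`, one row per reviewer decision on
#'   a conflicted record) and `resolutions` (tibble, initially empty).
#' @export
find_conflicts <- function(session) {
  d <- session$decisions
  if (length(unique(d$reviewer)) < 2) {
    stop_usage("conflict detection requires decisions from at least 2 reviewers")
  }
  per_record <- split(d, d$record_id)
  confl <- Filter(function(g) {
    length(unique(g$reviewer)) >= 2 && length(unique(g$decision)) >= 2
  }, per_record)
  conflicts <- if (length(confl) == 0) {
    tibble::tibble(record_id = character(0), reviewer = character(0),
                   decision = character(0))
  } else {
    all <- do.call(rbind, confl)
    tibble::tibble(record_id = all$record_id, reviewer = all$reviewer,
                   decision = all$decision)
  }
  structure(list(conflicts = conflicts,
                 resolutions = tibble::tibble(record_id = character(0),
                                              decision = character(0),
                                              comment = character(0))),
            class = "conflict_set")
}

#' @export
print.conflict_set <- function(x, ...) {
  cat(sprintf("<conflict_set> %d conflicted record(s)\n",
              length(unique(x$conflicts$record_id))))
  invisible(x)
}

#' Persist and resume a screening session
#'
#' The state file is JSON and holds the corpus fingerprint, configuration,
#' decisions, flags and the presented log — not the corpus or the trained
#' vectors. To resume, re-supply the same corpus and a model trained with
#' the same configuration and seed; the fingerprint is checked on load.
#'
#' @param session a screening session.
#' @param path JSON state file path.
#' @return `save_session()` returns `path` invisibly; `load_session()`
#'   returns the restored session.
#' @export
save_session <- function(session, path) {
  state <- list(
    corpus_ref = session$corpus_ref,
    seed_ids = session$seed_ids,
    round_size = session$round_size,
    halt_threshold = session$halt_threshold,
    aggregation = session$aggregation,
    round_index = session$round_index,
    decisions = as.data.frame(session$decisions),
    flags = session$flags,
    presented = as.data.frame(session$presented)
  )
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_session
#' @param corpus,model the corpus and vector model the session was built
#'   on (must match the stored fingerprint).
#' @export
load_session <- function(path, corpus, model) {
  if (!file.exists(path)) stop_data("session file '%s' does not exist", path)
  state <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(state$corpus_ref, corpus_fingerprint(corpus))) {
    stop_data("session file '%s' was created from a different corpus", path)
  }
  session <- init_session(corpus, model, state$seed_ids,
                          round_size = state$round_size,
                          halt_threshold = state$halt_threshold,
                          aggregation = state$aggregation)
  as_tbl <- function(x, template) {
    if (is.null(x) || length(x) == 0 || NROW(x) == 0) return(template)
    tibble::as_tibble(x)
  }
  session$decisions <- as_tbl(state$decisions, session$decisions)
  session$decisions$round <- as.integer(session$decisions$round)
  session$presented <- as_tbl(state$presented, session$presented)
  session$presented$round <- as.integer(session$presented$round)
  session$flags <- as.character(state$flags %||% character(0))
  refresh_round_index(session)
}
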