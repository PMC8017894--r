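#' Bundle a corpus with screening labels
#'
#' A labelled corpus carries the hindsight labels of a completed review:
#' `flagged_ids` are the articles flagged at title/abstract stage for
#' full-text review, and `final_ids` the subset included in the published
#' review after full-text screening (`final_ids` is a subset of
#' `flagged_ids`, which is a subset of the corpus).
#'
#' @param corpus a [new_corpus()] object.
#' @param flagged_ids,final_ids character vectors of record ids.
#' @return a `labelled_corpus` list.
#' @export
labelled_corpus <- function(corpus, flagged_ids, final_ids) {
  flagged_ids <- unique(as.character(flagged_ids))
  final_ids <- unique(as.character(final_ids))
  bad <- setdiff(flagged_ids, corpus$record_id)
  if (length(bad) > 0) {
    stop_data("flagged id(s) not in corpus: %s", paste(bad, collapse = ", "))
  }
  if (!all(final_ids %in% flagged_ids)) {
    stop_data("final_ids must be a subset of flagged_ids (offending: %s)",
              paste(setdiff(final_ids, flagged_ids), collapse = ", "))
  }
  structure(list(corpus = corpus, flagged_ids = flagged_ids,
                 final_ids = final_ids),
            class = "labelled_corpus")
}

#' @export
print.labelled_corpus <- function(x, ...) {
  cat(sprintf("<labelled_corpus> %d record(s), %d flagged, %d final\n",
              nrow(x$corpus), length(x$flagged_ids), length(x$final_ids)))
  invisible(x)
}

#' Replay a labelled corpus through the screening loop
#'
#' Simulates a reviewer screening a completed review with hindsight
#' labels: an automatic reviewer flags exactly the articles that were
#' flagged in the real abstract screen (even those that later failed
#' full-text review — that is the realistic feedback signal) and excludes
#' everything else. Seeds must come from the flagged set, are implicit
#' inclusions and are never screened. By default the replay stops at the
#' decision on which the last final article is found; `stop = "exhaust"`
#' screens the whole pool (needed for full recall curves and threshold
#' tables).
#'
#' @param labelled a [labelled_corpus()] with non-empty `final_ids`.
#' @param seed_ids non-empty subset of `flagged_ids` used as seeds.
#' @param model optional pre-trained [fit_vectorizer()] model; fitted on
#'   the fly otherwise.
#' @param method,round_size vectorizer method and round size.
#' @param rng_seed seed for model training (and any sampling), so
#'   identical inputs give byte-identical results.
#' @param stop `"last_final"` (default) or `"exhaust"`.
#' @param ... further arguments to [fit_vectorizer()].
#' @return a `simulation_result`: `seeds_used`, `rounds_completed`,
#'   `n_reviewed`, `n_not_reviewed` (pool remainder, so
#'   `n_reviewed + n_not_reviewed + |seeds| == N`), `trajectory` (recall
#'   curve over `final_ids`, counting final seeds as found at start),
#'   `halted_reason`, `screened_order`, and the input sizes.
#' @export
replay <- function(labelled, seed_ids, model = NULL,
                   method = c("tfidf", "paragraph"), round_size = 50,
                   rng_seed = 1L, stop = c("last_final", "exhaust"), ...) {
  method <- match.arg(method)
  stop <- match.arg(stop)
  seed_ids <- unique(as.character(seed_ids))
  if (length(seed_ids) == 0) stop_usage("at least 1 seed article is required")
  bad <- setdiff(seed_ids, labelled$flagged_ids)
  if (length(bad) > 0) {
    stop_usage("seed id(s) must be known-relevant (flagged) articles: %s",
               paste(bad, collapse = ", "))
  }
  if (length(labelled$final_ids) == 0) stop_usage("final_ids must be non-empty")
  if (is.null(model)) {
    model <- fit_vectorizer(labelled$corpus, method = method,
                            train_seed = rng_seed, ...)
  }

  targets <- setdiff(labelled$final_ids, seed_ids)
  found_at_start <- length(labelled$final_ids) - length(targets)
  session <- init_session(labelled$corpus, model, seed_ids,
                          round_size = round_size)

  screened <- character(0)
  n_reviewed <- 0L
  halted_reason <- NULL
  done <- length(targets) == 0 && stop == "last_final"
  if (done) halted_reason <- "all_final_found"

  while (!done) {
    nxt <- next_round(session)
    if (is.null(nxt)) break
    session <- nxt
    items <- current_round(session)$items$record_id
    if (stop == "last_final") {
      # decision granularity: stop on the decision that finds the last final
      remaining <- setdiff(targets, screened)
      hits <- which(items %in% remaining)
      if (length(hits) > 0 && length(setdiff(remaining, items)) == 0) {
        cut <- max(hits)
        items_taken <- items[seq_len(cut)]
        session <- decide_round_partial(session, "auto", items_taken,
                                        labelled$flagged_ids)
        screened <- c(screened, items_taken)
        n_reviewed <- n_reviewed + cut
        halted_reason <- "all_final_found"
        break
      }
    }
    session <- decide_round(session, "auto",
                            include_ids = labelled$flagged_ids,
                            flag_ids = labelled$flagged_ids)
    screened <- c(screened, items)
    n_reviewed <- n_reviewed + length(items)
  }
  if (is.null(halted_reason)) halted_reason <- "all_screened"

  n_pool <- nrow(labelled$corpus) - length(seed_ids)
  structure(
    list(
      seeds_used = seed_ids,
      rounds_completed = rounds_required(n_reviewed, round_size),
      n_reviewed = n_reviewed,
      n_not_reviewed = n_pool - n_reviewed,
      n_total = nrow(labelled$corpus),
      n_final = length(labelled$final_ids),
      n_flagged = length(labelled$flagged_ids),
      round_size = as.integer(round_size),
      trajectory = recall_trajectory(screened, targets,
                                     n_found_at_start = found_at_start),
      screened_order = screened,
      halted_reason = halted_reason,
      method = model$method,
      rng_seed = as.integer(rng_seed)
    ),
    class = "simulation_result"
  )
}

# Decide only the first records of the current round, in presentation
# order (used when the replay stops mid-round on the last final article).
decide_round_partial <- function(session, reviewer, items_taken, flagged_ids) {
  rnd <- session$current_round
  inc <- items_taken %in% flagged_ids
  session$decisions <- rbind(session$decisions, tibble::tibble(
    reviewer = as.character(reviewer), record_id = items_taken,
    decision = ifelse(inc, "include", "exclude"), flag = inc,
    round = rnd$round, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  ))
  session$flags <- unique(c(session$flags, items_taken[inc]))
  refresh_round_index(session)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> N = %d: %d seed(s), %d reviewed in %d round(s) of %d, %d not reviewed (%d%% of corpus not reviewed); halted: %s\n",
    x$n_total, length(x$seeds_used), x$n_reviewed, x$rounds_completed,
    x$round_size, x$n_not_reviewed,
    percent_not_reviewed(x$n_total, x$n_reviewed), x$halted_reason))
  invisible(x)
}

#' Threshold analysis: recall at fixed screened fractions
#'
#' Replays the corpus to exhaustion and reports how many final articles
#' are captured after screening 5%, 10%, ... of the corpus, plus work
#' saved over sampling at the 95% and 100% recall levels. This is the
#' analysis behind choosing an evidence-based stopping threshold.
#'
#' @param labelled a [labelled_corpus()].
#' @param seed_ids seeds, a subset of `flagged_ids`.
#' @param intervals screened fractions to tabulate (default 5% steps up
#'   to 35%).
#' @param ... passed to [replay()].
#' @return a `threshold_analysis`: list with `table` (tibble of
#'   `interval`, `n_screened`, `n_final_found`), `wss95`, `wss100`
#'   ([wss_at()] reports) and the underlying `result`.
#' @export
threshold_analysis <- function(labelled, seed_ids,
                               intervals = seq(0.05, 0.35, by = 0.05), ...) {
  res <- replay(labelled, seed_ids, stop = "exhaust", ...)
  traj <- res$trajectory
  n_start <- attr(traj, "n_start")
  N <- res$n_total
  tab <- tibble::tibble(
    interval = intervals,
    n_screened = vapply(intervals, function(p) {
      min(as.integer(ceiling(p * N)), nrow(traj))
    }, 0L),
    n_final_found = vapply(intervals, function(p) {
      k <- min(as.integer(ceiling(p * N)), nrow(traj))
      if (k == 0) n_start else as.integer(traj$n_found[k])
    }, 0L)
  )
  s95 <- screened_at_recall(traj, 0.95)
  s100 <- screened_at_recall(traj, 1.0)
  structure(
    list(table = tab,
         wss95 = wss_at(0.95, N, s95),
         wss100 = wss_at(1.0, N, s100),
         result = res),
    class = "threshold_analysis"
  )
}

#' @export
print.threshold_analysis <- function(x, ...) {
  cat(sprintf("<threshold_analysis> WSS@95 = %d%%, WSS@100 = %d%%\n",
              x$wss95$wss_percent, x$wss100$wss_percent))
  print(x$table)
  invisible(x)
}

#' Seed-sensitivity analysis
#'
#' How much do the number and combination of seed articles matter? For
#' each subset size `s`, replays the loop with every combination of `s`
#' seeds from `seed_pool` when there are at most `max_runs_per_size`
#' combinations, otherwise with a seeded random sample of
#' `max_runs_per_size` distinct combinations, and summarises the rounds
#' needed to reach full recall of the final articles.
#'
#' @param labelled a [labelled_corpus()].
#' @param seed_pool candidate seeds, a subset of `flagged_ids`.
#' @param subset_sizes integer vector of seed-set sizes to evaluate.
#' @param max_runs_per_size cap on replays per size (default 12).
#' @param rng_seed seed for combination sampling and model training.
#' @param model optional pre-trained model reused across replays.
#' @param ... passed to [replay()].
#' @return a `sensitivity_result`: tibble with one row per size —
#'   `size`, `median_rounds` (lower interpolation on even counts),
#'   `min_rounds`, `max_rounds`, `n_combinations_evaluated`,
#'   `n_combinations_total`.
#' @export
seed_sensitivity <- function(labelled, seed_pool, subset_sizes,
                             max_runs_per_size = 12, rng_seed = 1L,
                             model = NULL, ...) {
  if (length(subset_sizes) == 0) stop_usage("subset_sizes must be non-empty")
  seed_pool <- unique(as.character(seed_pool))
  bad <- setdiff(seed_pool, labelled$flagged_ids)
  if (length(bad) > 0) {
    stop_data("seed pool id(s) not in flagged set: %s", paste(bad, collapse = ", "))
  }
  if (any(subset_sizes < 1 | subset_sizes > length(seed_pool))) {
    stop_usage("subset sizes must lie in [1, |seed_pool|]")
  }
  if (is.null(model)) {
    model <- fit_vectorizer(labelled$corpus, train_seed = rng_seed)
  }

  rows <- lapply(as.integer(subset_sizes), function(s) {
    total <- choose(length(seed_pool), s)
    combos <- if (total <= max_runs_per_size) {
      asplit(utils::combn(seed_pool, s), 2)
    } else {
      sample_combinations(seed_pool, s, max_runs_per_size,
                          rng_seed + s)  # distinct per size, below 2^31
    }
    rounds <- vapply(combos, function(seeds) {
      replay(labelled, seeds, model = model, rng_seed = rng_seed, ...)$rounds_completed
    }, 0L)
    tibble::tibble(
      size = s,
      median_rounds = median_lower(rounds),
      min_rounds = min(rounds),
      max_rounds = max(rounds),
      n_combinations_evaluated = length(combos),
      n_combinations_total = total
    )
  })
  structure(list(rows = do.call(rbind, rows)), class = "sensitivity_result")
}

# Seeded sampling of distinct size-s combinations, without replacement.
sample_combinations <- function(pool, s, n, seed) {
  with_private_seed(seed, {
    seen <- character(0)
    out <- list()
    guard <- 0L
    while (length(out) < n && guard < 100L * n) {
      guard <- guard + 1L
      combo <- sort(sample(pool, s))
      key <- paste(combo, collapse = "\x1f")
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- combo
      }
    }
    out
  })
}

# Median with lower interpolation: the lower of the two middle order
# statistics on even counts, so the summary is always an observed value.
median_lower <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result>\n")
  print(x$rows)
  invisible(x)
}
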