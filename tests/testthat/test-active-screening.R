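small_session <- function(n = 20, seeds = 2, round_size = 5, rng_seed = 3) {
  lc <- generate_corpus(synthetic_spec(n_total = n, n_flagged = max(4, seeds + 2),
                                       n_final = 2, vocab_size = 150,
                                       abstract_length = 40, rng_seed = rng_seed))
  model <- fit_vectorizer(lc$corpus, "tfidf")
  list(lc = lc,
       session = init_session(lc$corpus, model, lc$flagged_ids[seq_len(seeds)],
                              round_size = round_size))
}

test_that("session initialization enforces seeds and round size", {
  lc <- generate_corpus(synthetic_spec(n_total = 100, n_flagged = 8, n_final = 3,
                                       vocab_size = 300, rng_seed = 2))
  model <- fit_vectorizer(lc$corpus, "tfidf")
  seeds <- lc$flagged_ids[1:2]
  session <- init_session(lc$corpus, model, seeds, round_size = 50)
  expect_equal(session$round_index, 0L)
  expect_equal(nrow(session$decisions), 0L)
  expect_length(screenloop:::screenable_ids(session), 98)
  expect_error(init_session(lc$corpus, model, "NOPE123"), "NOPE123",
               class = "screenloop_data_error")
  expect_error(init_session(lc$corpus, model, character(0)),
               class = "screenloop_usage_error")
  expect_error(init_session(lc$corpus, model, seeds, round_size = 0),
               class = "screenloop_usage_error")
})

test_that("relevance scores are max-cosine to the relevant exemplars", {
  corpus <- make_corpus(
    titles = c("sleep quality and exercise", "sleep quality and exercise",
               "tomato cultivar genetics", "exercise during pregnancy",
               "quality of sleep exercise trial"),
    abstracts = rep("", 5)
  )
  model <- fit_vectorizer(corpus, "tfidf")
  session <- init_session(corpus, model, "R001", round_size = 4)
  scores <- relevance_scores(session)
  # a textual twin of the seed scores exactly 1
  expect_equal(unname(scores["R002"]), 1, tolerance = 1e-12)
  # no shared vocabulary scores exactly 0
  expect_equal(unname(scores["R003"]), 0)
  # every score matches the by-definition oracle
  oracle <- oracle_scores(oracle_tfidf(oracle_tokens(corpus)),
                          pool = names(scores), relevant = "R001")
  expect_lt(max(abs(scores - oracle[names(scores)])), 1e-9)
})

test_that("rounds partition the pool: sizes 50 then 48 for 98 screenable", {
  fx <- small_session(n = 100, seeds = 2, round_size = 50)
  s <- next_round(fx$session)
  expect_equal(nrow(current_round(s)$items), 50)
  s <- decide_round(s, "r1", include_ids = character(0))
  s2 <- next_round(s)
  expect_equal(nrow(current_round(s2)$items), 48)
  # concatenation of rounds is a permutation of the screenable pool
  presented <- s2$presented$record_id
  expect_setequal(presented, screenloop:::screenable_ids(fx$session))
  expect_false(anyDuplicated(presented) > 0)
  # pool exhausted afterwards
  s2 <- decide_round(s2, "r1", include_ids = character(0))
  expect_null(next_round(s2))
})

test_that("ranking is stable when no new flags arrive and shifts when they do", {
  fx <- small_session(n = 30, seeds = 1, round_size = 5)
  s <- next_round(fx$session)
  first <- current_round(s)$items$record_id
  # no flags: the remaining ordering is a deterministic function of the model
  sA <- decide_round(s, "r1", include_ids = character(0))
  sB <- decide_round(s, "r1", include_ids = character(0))
  expect_identical(current_round(next_round(sA))$items,
                   current_round(next_round(sB))$items)
  # flagging feeds the next re-ranking
  flagged_in_round <- intersect(first, fx$lc$flagged_ids)
  sF <- decide_round(s, "r1", include_ids = flagged_in_round)
  expect_setequal(sF$flags, flagged_in_round)
})

test_that("seeded synthetic corpus front-loads the relevant articles in round 1", {
  lc <- generate_corpus(synthetic_spec(n_total = 120, n_flagged = 6, n_final = 6,
                                       vocab_size = 500, topic_injection_rate = 0.8,
                                       abstract_length = 60, rng_seed = 21))
  model <- fit_vectorizer(lc$corpus, "tfidf")
  seed <- lc$flagged_ids[1]
  session <- next_round(init_session(lc$corpus, model, seed, round_size = 50))
  round1 <- current_round(session)$items
  remaining_relevant <- setdiff(lc$flagged_ids, seed)
  expect_gte(sum(remaining_relevant %in% round1$record_id), 4)
  # round composition equals the brute-force max-cosine oracle
  oracle <- oracle_replay(lc$corpus, seed, lc$flagged_ids, lc$final_ids, 50)
  expect_identical(round1$record_id, oracle$order[1:50])
})

test_that("decisions are validated for sequencing, duplication and flag misuse", {
  fx <- small_session(n = 20, seeds = 1, round_size = 5)
  s <- next_round(fx$session)
  ids <- current_round(s)$items$record_id
  unpresented <- setdiff(screenloop:::screenable_ids(s), ids)[1]
  expect_error(record_decision(s, "r1", unpresented, "include"),
               "not been presented", class = "screenloop_usage_error")
  s <- record_decision(s, "r1", ids[1], "include", flag = TRUE)
  expect_equal(s$flags, ids[1])
  expect_error(record_decision(s, "r1", ids[1], "exclude"),
               "already decided", class = "screenloop_usage_error")
  expect_error(record_decision(s, "r1", ids[2], "exclude", flag = TRUE),
               class = "screenloop_usage_error")
  # excluding removes from the pool without touching the relevant set
  s <- record_decision(s, "r1", ids[2], "exclude")
  expect_equal(s$flags, ids[1])
  # round completes -> round_index advances
  for (id in ids[3:5]) s <- record_decision(s, "r1", id, "exclude")
  expect_equal(s$round_index, 1L)
})

test_that("halting fires on pool exhaustion or at the agreed threshold", {
  fx <- small_session(n = 110, seeds = 10, round_size = 50)
  s <- fx$session
  s$halt_threshold <- 0.5
  expect_equal(halt_check(s)$status, "continue")
  s <- decide_round(next_round(s), "r1", include_ids = character(0))
  hc <- halt_check(s)  # 50 of 100 decided
  expect_equal(hc$status, "halt")
  expect_equal(hc$reason, "threshold_reached")
  # a 3600-article pool at a 50% threshold is 36 rounds of 50
  expect_equal(rounds_required(0.5 * 3600, 50), 36)

  s2 <- fx$session  # no threshold: runs to exhaustion
  repeat {
    nx <- next_round(s2)
    if (is.null(nx)) break
    s2 <- decide_round(nx, "r1", include_ids = character(0))
  }
  hc2 <- halt_check(s2)
  expect_equal(hc2$reason, "all_screened")
  expect_equal(length(unique(s2$decisions$record_id)), 100)
})

test_that("conflicts are exactly the non-unanimous multi-reviewer decisions", {
  fx <- small_session(n = 20, seeds = 1, round_size = 5)
  s <- next_round(fx$session)
  ids <- current_round(s)$items$record_id
  expect_error(find_conflicts(s), class = "screenloop_usage_error")
  s <- record_decision(s, "alice", ids[1], "include")
  s <- record_decision(s, "bob", ids[1], "exclude")     # conflict
  s <- record_decision(s, "alice", ids[2], "include")
  s <- record_decision(s, "bob", ids[2], "include")     # unanimous
  s <- record_decision(s, "alice", ids[3], "exclude")   # single reviewer
  cs <- find_conflicts(s)
  expect_equal(unique(cs$conflicts$record_id), ids[1])
  expect_setequal(cs$conflicts$decision, c("include", "exclude"))
})

test_that("sessions persist to JSON and resume identically", {
  fx <- small_session(n = 30, seeds = 2, round_size = 10, rng_seed = 8)
  s <- next_round(fx$session)
  ids <- current_round(s)$items$record_id
  s <- decide_round(s, "r1", include_ids = ids[1:2])
  path <- withr::local_tempfile(fileext = ".json")
  save_session(s, path)
  model <- fit_vectorizer(fx$lc$corpus, "tfidf")
  restored <- load_session(path, fx$lc$corpus, model)
  expect_equal(restored$round_index, s$round_index)
  expect_equal(restored$flags, s$flags)
  expect_equal(restored$presented$record_id, s$presented$record_id)
  # the next round after resuming equals the uninterrupted continuation
  expect_identical(current_round(next_round(restored))$items,
                   current_round(next_round(s))$items)
  # wrong corpus is rejected
  other <- generate_corpus(synthetic_spec(n_total = 30, n_flagged = 4,
                                          n_final = 2, rng_seed = 99))
  expect_error(load_session(path, other$corpus, model),
               class = "screenloop_data_error")
})
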