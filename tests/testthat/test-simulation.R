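test_that("replay stops immediately when the seeds already cover the finals", {
  lc <- generate_corpus(synthetic_spec(n_total = 60, n_flagged = 6, n_final = 2,
                                       vocab_size = 200, rng_seed = 14))
  res <- replay(lc, seed_ids = lc$final_ids)
  expect_equal(res$rounds_completed, 0L)
  expect_equal(res$n_reviewed, 0L)
  expect_equal(res$halted_reason, "all_final_found")
  expect_equal(res$n_not_reviewed, 60 - length(lc$final_ids))
})

test_that("replay validates its seed and label preconditions", {
  lc <- generate_corpus(synthetic_spec(n_total = 40, n_flagged = 5, n_final = 2,
                                       vocab_size = 200, rng_seed = 15))
  decoy <- setdiff(lc$corpus$record_id, lc$flagged_ids)[1]
  expect_error(replay(lc, decoy), decoy, class = "screenloop_usage_error")
  expect_error(replay(lc, character(0)), class = "screenloop_usage_error")
  no_final <- labelled_corpus(lc$corpus, lc$flagged_ids, character(0))
  expect_error(replay(no_final, lc$flagged_ids[1]),
               class = "screenloop_usage_error")
})

test_that("an adversarial final with disjoint vocabulary is still recovered", {
  lc <- generate_corpus(synthetic_spec(n_total = 50, n_flagged = 5, n_final = 2,
                                       vocab_size = 200, rng_seed = 16))
  corpus <- lc$corpus
  # rewrite one final article so it shares no vocabulary with anything
  adv <- setdiff(lc$final_ids, lc$flagged_ids[1])[1]
  corpus$title[corpus$record_id == adv] <- "zzqqxx yyrrww vvttuu"
  corpus$abstract[corpus$record_id == adv] <- "qqzz wwrr ttvv uuyy"
  lc2 <- labelled_corpus(corpus, lc$flagged_ids, lc$final_ids)
  res <- replay(lc2, lc$flagged_ids[1], round_size = 10)
  expect_equal(max(res$trajectory$n_found), attr(res$trajectory, "n_final"))
  expect_lte(res$n_reviewed, 49)
  expect_equal(res$halted_reason, "all_final_found")
})

test_that("replay matches the brute-force sort-and-step oracle exactly", {
  lc <- generate_corpus(synthetic_spec(n_total = 150, n_flagged = 10, n_final = 5,
                                       vocab_size = 600, abstract_length = 60,
                                       rng_seed = 23))
  seeds <- lc$flagged_ids[1:2]
  res <- replay(lc, seeds, round_size = 25)
  oracle <- oracle_replay(lc$corpus, seeds, lc$flagged_ids, lc$final_ids,
                          round_size = 25)
  expect_equal(res$n_reviewed, oracle$n_reviewed_at_last_final)
  expect_identical(res$screened_order,
                   oracle$order[seq_len(res$n_reviewed)])
  exhaust <- replay(lc, seeds, round_size = 25, stop = "exhaust")
  expect_identical(exhaust$screened_order, oracle$order)
})

test_that("every replay satisfies the reviewed + not-reviewed + seeds identity", {
  for (i in 1:5) {
    lc <- generate_corpus(synthetic_spec(n_total = 80, n_flagged = 8, n_final = 3,
                                         vocab_size = 300, abstract_length = 50,
                                         rng_seed = 30 + i))
    n_seeds <- 1 + i %% 3
    res <- replay(lc, lc$flagged_ids[seq_len(n_seeds)], round_size = 20)
    expect_equal(res$n_reviewed + res$n_not_reviewed + n_seeds, 80)
    expect_equal(max(res$trajectory$n_found), attr(res$trajectory, "n_final"))
  }
})

test_that("identical inputs give identical simulation results", {
  lc <- generate_corpus(synthetic_spec(n_total = 70, n_flagged = 7, n_final = 3,
                                       vocab_size = 300, rng_seed = 40))
  r1 <- replay(lc, lc$flagged_ids[1], rng_seed = 5)
  r2 <- replay(lc, lc$flagged_ids[1], rng_seed = 5)
  expect_identical(r1, r2)
  p1 <- replay(lc, lc$flagged_ids[1], method = "paragraph", rng_seed = 5,
               dimension = 20, epochs = 5)
  p2 <- replay(lc, lc$flagged_ids[1], method = "paragraph", rng_seed = 5,
               dimension = 20, epochs = 5)
  expect_identical(p1, p2)
})

test_that("a round as large as the pool reduces to a single exhaustive round", {
  lc <- generate_corpus(synthetic_spec(n_total = 40, n_flagged = 5, n_final = 3,
                                       vocab_size = 200, rng_seed = 41))
  seed <- lc$flagged_ids[1]
  has_nonseed_final <- length(setdiff(lc$final_ids, seed)) > 0
  res <- replay(lc, seed, round_size = 39)
  expect_true(has_nonseed_final)
  expect_equal(res$rounds_completed, 1L)
})

test_that("threshold analysis saturates monotonically and resamples the trajectory", {
  lc <- generate_corpus(synthetic_spec(n_total = 100, n_flagged = 8, n_final = 4,
                                       vocab_size = 400, topic_injection_rate = 0.9,
                                       rng_seed = 50))
  ta <- threshold_analysis(lc, lc$flagged_ids[1], round_size = 20)
  tab <- ta$table
  expect_true(all(diff(tab$n_final_found) >= 0))
  expect_lte(max(tab$n_final_found), 4)
  # direct resampling oracle: counts at ceil(p * N) positions of the full order
  res <- ta$result
  n_start <- attr(res$trajectory, "n_start")
  for (k in seq_len(nrow(tab))) {
    pos <- min(ceiling(tab$interval[k] * 100), length(res$screened_order))
    found <- sum(res$screened_order[seq_len(pos)] %in%
                   setdiff(lc$final_ids, res$seeds_used)) + n_start
    expect_equal(tab$n_final_found[k], found)
  }
  # with a strong signal everything is found early; later intervals repeat |final|
  if (tab$n_final_found[1] == 4) {
    expect_true(all(tab$n_final_found == 4))
  }
  expect_s3_class(ta$wss95, "wss_report")
  expect_gte(ta$wss100$wss, 0)
})

test_that("seed sensitivity enumerates combinations exactly when feasible", {
  lc <- generate_corpus(synthetic_spec(n_total = 60, n_flagged = 12, n_final = 3,
                                       vocab_size = 300, abstract_length = 40,
                                       rng_seed = 60))
  model <- fit_vectorizer(lc$corpus, "tfidf")
  res <- seed_sensitivity(lc, lc$flagged_ids, subset_sizes = c(12, 11),
                          max_runs_per_size = 12, model = model, round_size = 20)
  rows <- res$rows
  # all 12 seeds: a single combination; leave-one-out: twelve combinations
  expect_equal(rows$n_combinations_evaluated[rows$size == 12], 1)
  expect_equal(rows$n_combinations_total[rows$size == 12], 1)
  expect_equal(rows$n_combinations_evaluated[rows$size == 11], 12)
  expect_equal(rows$n_combinations_total[rows$size == 11], 12)
  expect_true(all(rows$min_rounds <= rows$median_rounds &
                    rows$median_rounds <= rows$max_rounds))
})

test_that("seed sensitivity samples distinct combinations when enumeration is too big", {
  lc <- generate_corpus(synthetic_spec(n_total = 50, n_flagged = 10, n_final = 3,
                                       vocab_size = 300, abstract_length = 40,
                                       rng_seed = 61))
  model <- fit_vectorizer(lc$corpus, "tfidf")
  res <- seed_sensitivity(lc, lc$flagged_ids, subset_sizes = 3,
                          max_runs_per_size = 5, model = model,
                          rng_seed = 7, round_size = 20)
  expect_equal(res$rows$n_combinations_evaluated, 5)
  expect_equal(res$rows$n_combinations_total, choose(10, 3))
  res2 <- seed_sensitivity(lc, lc$flagged_ids, subset_sizes = 3,
                           max_runs_per_size = 5, model = model,
                           rng_seed = 7, round_size = 20)
  expect_identical(res$rows, res2$rows)  # seeded sampling
  expect_error(seed_sensitivity(lc, lc$flagged_ids, integer(0)),
               class = "screenloop_usage_error")
})

test_that("median uses lower interpolation on even counts", {
  expect_equal(screenloop:::median_lower(c(4, 1, 3, 2)), 2)
  expect_equal(screenloop:::median_lower(c(5, 1, 3)), 3)
  expect_equal(screenloop:::median_lower(7), 7)
})
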