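test_that("delta-rule update follows the prediction-error form", {
  expect_equal(update_performance(5, 9, 0.5), 7)
  expect_equal(update_performance(5, 9, 1.0), 9)
  expect_equal(update_performance(5, 9, 0), 5)
  x <- c(1, 7.3, 15)
  expect_equal(update_performance(x, x, 0.4), x)
  expect_error(update_performance(5, 9, 1.2),
               class = "somtrack_invalid_parameter")
})

test_that("rating softmax is the logistic of beta * (perf - marker)", {
  expect_equal(p_positive_rating(7.5, 7.5, 2), 0.5)
  expect_equal(p_positive_rating(8.5, 7.5, 1), exp(1) / (exp(1) + 1))
  expect_equal(p_positive_rating(9, 7.5, 500), 1, tolerance = 1e-12)
  expect_gt(p_positive_rating(9, 7.5, 1), p_positive_rating(8, 7.5, 1))
  expect_error(p_positive_rating(8, 7.5, 0),
               class = "somtrack_invalid_parameter")
})

test_that("rating expected value is bounded by the bonus and zero when negative", {
  expect_equal(ev_rating(1.0, 1), 0.25)
  expect_equal(ev_rating(0.0, 1), -0.25)
  expect_equal(ev_rating(0.5, 1), 0)
  expect_equal(ev_rating(0.9, 0), 0)
  expect_equal(ev_rating(0.9, "negative"), 0)
  p <- seq(0, 1, by = 0.1)
  expect_true(all(abs(ev_rating(p, 1)) <= 0.25))
})

test_that("engage EV and choice probability follow the softmax over EV_avoid = 0", {
  expect_equal(ev_engage(10, 6, 2, context = -1), 2)
  expect_equal(ev_engage(10, 6, 8, context = +1), 0)
  expect_equal(ev_engage(9, 9, 0, context = -1), 0)
  expect_equal(p_engage(0, 1), 0.5)
  expect_equal(p_engage(1, 1), exp(1) / (exp(1) + 1))
  expect_equal(p_engage(-50, 2), 0, tolerance = 1e-12)
})

test_that("chosen EV sums the three components and RPE is reward minus it", {
  r <- ev_chosen_and_rpe(0, 0, 0, reward = 1.5)
  expect_equal(r$EV_chosen, 0)
  expect_equal(r$RPE, 1.5)
  r <- ev_chosen_and_rpe(0.1, -0.05, 2.0, reward = 1.5)
  expect_equal(r$EV_chosen, 2.05)
  expect_equal(r$RPE, -0.55)
  r <- ev_chosen_and_rpe(0.2, 0.1, 1, reward = 1.3)
  expect_equal(r$RPE, 0)
})

# A minimal hand-built session: one main trial where every modeled
# probability of the observed decisions is exactly 0.5.
indifferent_record <- function() {
  starter <- tibble::tibble(
    session_id = "x", trial_index = 1:4, phase = "starter",
    minigame = rep(c("game1", "game2"), 2),
    context = c(1, -1, 1, -1), relevant_other = "O1",
    threshold = 0, feedback_S = 7.5, feedback_O1 = 7.5, feedback_O2 = 7.5,
    false_start = FALSE, has_decisions = FALSE,
    rating_S = NA_integer_, rating_O = NA_integer_,
    marker_S = NA_real_, marker_O = NA_real_,
    choice = NA_character_, payoff = NA_real_
  )
  main <- tibble::tibble(
    session_id = "x", trial_index = 5L, phase = "main",
    minigame = "game1", context = -1, relevant_other = "O1",
    threshold = 0, feedback_S = 7.5, feedback_O1 = 7.5, feedback_O2 = 7.5,
    false_start = FALSE, has_decisions = TRUE,
    rating_S = 1L, rating_O = 0L, marker_S = 7.5, marker_O = 7.5,
    choice = "engage", payoff = 0
  )
  dplyr::bind_rows(starter, main)
}

test_that("session_nll has the closed form 3 log 2 at full indifference", {
  rec <- indifferent_record()
  expect_equal(session_nll(rec, alpha = 0.3, beta = 0.8), 3 * log(2),
               tolerance = 1e-12)
  # finite for extreme parameters thanks to the probability floor
  expect_true(is.finite(session_nll(rec, alpha = 1, beta = 20)))
  expect_error(session_nll(rec, alpha = 1.5, beta = 1),
               class = "somtrack_invalid_parameter")
})

test_that("session_nll matches an independent straight-line oracle", {
  cases <- list(
    list(seed = 1, alpha = 0.3, beta = 0.8, pfs = 0),
    list(seed = 2, alpha = 0.7, beta = 0.4, pfs = 0.08),
    list(seed = 3, alpha = 0.05, beta = 2.5, pfs = 0),
    list(seed = 4, alpha = 1.0, beta = 1.0, pfs = 0.1),
    list(seed = 5, alpha = 0.45, beta = 0.1, pfs = 0)
  )
  for (cs in cases) {
    rec <- make_session(
      seed = cs$seed, n_main = 40, n_starter = 8,
      params = agent_params(0.3, 0.8, w_som_StoO = 0.2,
                            p_false_start = cs$pfs))
    expect_equal(session_nll(rec, cs$alpha, cs$beta),
                 oracle_session_nll(rec, cs$alpha, cs$beta),
                 tolerance = 1e-8)
  }
})

test_that("latent traces obey the no-learning and full-update limits", {
  rec <- make_session(seed = 17, n_main = 32, n_starter = 8)
  main <- dplyr::filter(rec, phase == "main")
  starter <- dplyr::filter(rec, phase == "starter")

  tr0 <- trace_latents(rec, alpha = 0, beta = 1)
  for (mg in c("game1", "game2")) {
    init <- tail(starter$feedback_S[starter$minigame == mg], 1)
    expect_true(all(tr0$S_performance[main$minigame == mg] == init))
  }

  tr1 <- trace_latents(rec, alpha = 1, beta = 1)
  for (mg in c("game1", "game2")) {
    idx <- which(main$minigame == mg)
    init <- tail(starter$feedback_S[starter$minigame == mg], 1)
    expected <- c(init, head(main$feedback_S[idx], -1))
    expect_equal(tr1$S_performance[idx], as.numeric(expected))
  }

  # determinism of the replay
  expect_identical(trace_latents(rec, 0.3, 0.8), trace_latents(rec, 0.3, 0.8))
})

test_that("false starts freeze the self estimate and drop the self PE", {
  rec <- make_session(seed = 23, n_main = 48, n_starter = 8,
                      params = agent_params(0.3, 0.8, p_false_start = 0.15))
  main <- dplyr::filter(rec, phase == "main")
  expect_gt(sum(main$false_start), 0)
  tr <- trace_latents(rec, 0.4, 1)
  expect_true(all(is.na(tr$PE_S[main$false_start])))
  expect_true(all(!is.na(tr$PE_O[main$false_start])))
  # the estimate entering the trial after a false start equals the one
  # entering the false-start trial (same minigame)
  for (i in which(main$false_start)) {
    mg <- main$minigame[i]
    later <- which(main$minigame == mg & seq_len(nrow(main)) > i)
    if (length(later) == 0) next
    j <- later[1]
    # no intervening update of S for this minigame
    expect_equal(tr$S_performance[j], tr$S_performance[i])
    break
  }
})

test_that("duplicating every session leaves the fitted optimum unchanged", {
  rec <- make_session(seed = 29, n_main = 24, n_starter = 8)
  trials <- dplyr::bind_rows(
    dplyr::mutate(rec, session_id = "a"),
    dplyr::mutate(rec, session_id = "b")
  )
  f1 <- fit_group(dplyr::mutate(rec, session_id = "a"))
  f2 <- fit_group(trials)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-3)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-3)
  expect_equal(2 * f1$nll, f2$nll, tolerance = 1e-4)
})

test_that("tidy and glance summarise a fit", {
  rec <- make_session(seed = 31, n_main = 24, n_starter = 8)
  f <- fit_group(rec)
  td <- tidy(f)
  expect_equal(td$term, c("alpha", "beta"))
  gl <- glance(f)
  expect_equal(gl$n_sessions, 1L)
  expect_equal(gl$n_decisions, 3L * sum(rec$has_decisions & rec$phase == "main"))
})
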