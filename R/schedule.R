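#' Generate the crossed trial design of one session
#'
#' Builds the trial table for a single session of the social
#' performance-tracking task: a starter phase (first trials without
#' decisions, for impression formation) followed by a main phase with a
#' fully crossed 2 (context: cooperation/competition) x 2 (relevant other:
#' O1/O2) x 2 (minigame) design in pseudorandom order. Feedback and
#' thresholds are filled in by [generate_feedback_schedule()] and
#' [generate_thresholds()].
#'
#' @param seed Integer seed; the schedule is a pure function of it.
#' @param n_main Number of main-phase trials; must be divisible by 8 so that
#'   every design cell receives exactly `n_main / 8` trials.
#' @param n_starter Number of starter-phase trials (>= 4). The first four
#'   starter trials carry no decisions (no ratings, no engage/avoid choice)
#'   and always cover both minigames twice each.
#' @param session_id Label stored in the `session_id` column.
#' @return A tibble with one row per trial and columns `session_id`,
#'   `trial_index`, `phase` (`"starter"`/`"main"`), `minigame`, `context`
#'   (+1 cooperation, -1 competition), `relevant_other`, `threshold`,
#'   `feedback_S`, `feedback_O1`, `feedback_O2`, `false_start`,
#'   `has_decisions`.
#' @examples
#' sched <- generate_schedule(seed = 1)
#' dplyr::count(dplyr::filter(sched, phase == "main"),
#'              context, relevant_other, minigame)
#' @export
generate_schedule <- function(seed, n_main = 88L, n_starter = 16L,
                              session_id = "S1") {
  if (n_main %% 8 != 0) {
    abort(sprintf(
      "`n_main` (%d) must be divisible by 8 for a balanced crossed design.",
      n_main), class = "somtrack_invalid_design")
  }
  if (n_starter < 4) {
    abort("`n_starter` must be at least 4 (the no-decision starter trials).",
          class = "somtrack_invalid_design")
  }

  cells <- tidyr::expand_grid(
    context = c(1, -1),
    relevant_other = c("O1", "O2"),
    minigame = .minigames
  )

  withr::with_seed(seed, {
    main <- cells[rep(seq_len(nrow(cells)), each = n_main / 8L), ]
    main <- main[sample.int(nrow(main)), ]

    # Starter phase: as balanced over cells as n_starter allows.
    reps <- ceiling(n_starter / 8L)
    starter_pool <- cells[rep(seq_len(nrow(cells)), each = reps), ]
    starter <- starter_pool[sample.int(nrow(starter_pool), n_starter), ]
    # The four no-decision trials must cover both minigames twice each so
    # every player x minigame estimate is seeded before the first rating.
    i_g1 <- which(starter$minigame == "game1")
    i_g2 <- which(starter$minigame == "game2")
    if (length(i_g1) < 2 || length(i_g2) < 2) {
      # Re-deal degenerate draws (possible only for tiny n_starter).
      starter$minigame <- rep(.minigames, length.out = n_starter)
      i_g1 <- which(starter$minigame == "game1")
      i_g2 <- which(starter$minigame == "game2")
    }
    first4 <- c(i_g1[1:2], i_g2[1:2])
    starter <- dplyr::bind_rows(starter[first4, ], starter[-first4, ])
    # Interleave the two minigames in the opening trials: g1 g2 g1 g2.
    starter[1:4, ] <- starter[c(1, 3, 2, 4), ]
  })

  trials <- dplyr::bind_rows(
    dplyr::mutate(starter, phase = "starter"),
    dplyr::mutate(main, phase = "main")
  )
  trials <- dplyr::mutate(
    trials,
    session_id = session_id,
    trial_index = dplyr::row_number(),
    threshold = NA_real_,
    feedback_S = NA_integer_,
    feedback_O1 = NA_integer_,
    feedback_O2 = NA_integer_,
    false_start = FALSE,
    has_decisions = !(.data$phase == "starter" & .data$trial_index <= 4)
  )
  dplyr::select(
    trials, "session_id", "trial_index", "phase", "minigame", "context",
    "relevant_other", "threshold", "feedback_S", "feedback_O1",
    "feedback_O2", "false_start", "has_decisions"
  )
}

#' Fill a schedule with slowly drifting performance feedback
#'
#' Emulates the task's pre-determined feedback schedules: for each player and
#' minigame a latent ability level performs a bounded random walk (abilities
#' are stable but drift slowly), and the presented feedback is the level plus
#' observation noise, rounded to integers and clipped to the 1-15 scale.
#' Because the two minigames are interleaved in pseudorandom order, the
#' presented feedback stream has weaker lag-1 autocorrelation than either
#' within-minigame series.
#'
#' @param schedule A trial table from [generate_schedule()].
#' @param seed Integer seed.
#' @param drift_sd Standard deviation of the per-trial random-walk step of the
#'   latent level (performance-scale points).
#' @param obs_sd Standard deviation of the observation noise added before
#'   rounding.
#' @param level_means Optional 3 x 2 numeric matrix (rows `S`, `O1`, `O2`;
#'   columns `game1`, `game2`) of starting latent levels, all within 1-15.
#'   By default drawn from a truncated normal centred mid-scale.
#' @return The schedule with `feedback_S`, `feedback_O1`, `feedback_O2`
#'   filled with integers in 1-15.
#' @export
generate_feedback_schedule <- function(schedule, seed, drift_sd = 0.35,
                                       obs_sd = 1.2, level_means = NULL) {
  n <- nrow(schedule)
  seeds <- derive_seeds(seed, 2L)
  if (is.null(level_means)) {
    level_means <- withr::with_seed(
      seeds[1],
      matrix(rtnorm(6, mean = .SCALE_MID, sd = 2, lower = 4, upper = 12),
             nrow = 3, dimnames = list(.players, .minigames))
    )
  } else {
    level_means <- as.matrix(level_means)
    dimnames(level_means) <- list(.players, .minigames)
    if (any(level_means < .SCALE_MIN | level_means > .SCALE_MAX)) {
      abort("`level_means` must lie within the 1-15 performance scale.",
            class = "somtrack_invalid_parameter")
    }
  }

  fb <- matrix(NA_integer_, nrow = n, ncol = 3,
               dimnames = list(NULL, .players))
  withr::with_seed(seeds[2], {
    for (mg in .minigames) {
      rows <- which(schedule$minigame == mg)
      k <- length(rows)
      if (k == 0) next
      for (pl in .players) {
        steps <- rnorm(k, 0, drift_sd)
        level <- numeric(k)
        cur <- level_means[pl, mg]
        for (t in seq_len(k)) {
          cur <- min(max(cur + steps[t], .SCALE_MIN), .SCALE_MAX)
          level[t] <- cur
        }
        obs <- round(level + rnorm(k, 0, obs_sd))
        fb[rows, pl] <- as.integer(pmin(pmax(obs, .SCALE_MIN), .SCALE_MAX))
      }
    }
  })
  schedule$feedback_S <- fb[, "S"]
  schedule$feedback_O1 <- fb[, "O1"]
  schedule$feedback_O2 <- fb[, "O2"]
  schedule
}

#' Fill a schedule with engage/avoid thresholds
#'
#' The threshold of each trial is constructed from the scheduled feedback of
#' that trial -- the feedback difference (self minus relevant other) in
#' competition, the feedback mean in cooperation -- plus zero-mean Gaussian
#' noise. The engage payoff (payoff-relevant quantity minus threshold) is
#' therefore centred near zero and decorrelated from the players' ability
#' levels, dissociating reward expectation from performance expectation.
#'
#' @param schedule A trial table with feedback already filled.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of the threshold noise; must be > 0
#'   (thresholds must vary unpredictably).
#' @return The schedule with `threshold` filled.
#' @export
generate_thresholds <- function(schedule, seed, noise_sd = 2) {
  if (noise_sd <= 0) {
    abort("`noise_sd` must be positive: thresholds must vary from trial to trial.",
          class = "somtrack_invalid_parameter")
  }
  if (anyNA(schedule$feedback_S)) {
    abort("Feedback must be filled before thresholds (run generate_feedback_schedule()).",
          class = "somtrack_invalid_input")
  }
  fo <- ifelse(schedule$relevant_other == "O1",
               schedule$feedback_O1, schedule$feedback_O2)
  base <- ifelse(schedule$context < 0,
                 schedule$feedback_S - fo,
                 (schedule$feedback_S + fo) / 2)
  schedule$threshold <- base +
    withr::with_seed(seed, rnorm(nrow(schedule), 0, noise_sd))
  schedule
}

#' Payoff of an engage choice
#'
#' Competition pays the feedback difference (self minus relevant other) minus
#' the threshold; cooperation pays the feedback mean minus the threshold.
#' Vectorised.
#'
#' @param feedback_S,feedback_O Performance feedback for self and the
#'   relevant other.
#' @param threshold Trial threshold.
#' @param context +1 for cooperation, -1 for competition.
#' @return Numeric payoff(s).
#' @examples
#' engage_payoff(10, 6, 2, context = -1)  # competition: (10 - 6) - 2 = 2
#' engage_payoff(10, 6, 8, context = +1)  # cooperation: (10 + 6)/2 - 8 = 0
#' @export
engage_payoff <- function(feedback_S, feedback_O, threshold, context) {
  n <- max(length(feedback_S), length(feedback_O), length(threshold),
           length(context))
  context <- rep_len(context, n)
  ifelse(context < 0,
         (feedback_S - feedback_O) - threshold,
         (feedback_S + feedback_O) / 2 - threshold)
}

#' Realised payoff of one trial's engage/avoid choice
#'
#' False-start trials pay a fixed loss of 3 points regardless of the choice.
#' Avoiding pays +1.5 or -1.5 with equal probability (zero expected value).
#' Engaging pays [engage_payoff()]. Rating bonuses are settled separately.
#'
#' @param choice `"engage"` or `"avoid"` (vectorised).
#' @param feedback_S,feedback_O,threshold,context As in [engage_payoff()].
#' @param false_start Logical; fixed -3 payoff when `TRUE`.
#' @param u Uniform draws on (0, 1) deciding the avoid lottery; supplied so
#'   callers control the RNG stream. Defaults to fresh draws.
#' @return Numeric payoff(s).
#' @export
settle_trial <- function(choice, feedback_S, feedback_O, threshold, context,
                         false_start = FALSE, u = runif(length(choice))) {
  n <- length(choice)
  avoid_pay <- ifelse(rep_len(u, n) < 0.5, 1.5, -1.5)
  pay <- ifelse(choice == "engage",
                engage_payoff(feedback_S, feedback_O, threshold, context),
                avoid_pay)
  ifelse(rep_len(false_start, n), -3, pay)
}

#' Staircase update of a rating marker
#'
#' A positive rating moves the marker up one point for the next trial of the
#' same minigame and player, a negative rating down one point; the marker
#' stays on the half-integer grid and is clipped to \[1.5, 14.5\] so that both
#' rating responses always remain meaningful.
#'
#' @param marker Current marker value (X.5 grid within \[1.5, 14.5\]).
#' @param rating 1 (positive) or 0 (negative); `"positive"`/`"negative"`
#'   also accepted.
#' @return Updated marker value.
#' @examples
#' update_rating_marker(7.5, 1)   # 8.5
#' update_rating_marker(1.5, 0)   # clipped at 1.5
#' @export
update_rating_marker <- function(marker, rating) {
  if (is.character(rating)) rating <- as.integer(rating == "positive")
  if (!all(on_marker_grid(marker))) {
    abort("`marker` must lie on the X.5 grid within [1.5, 14.5].",
          class = "somtrack_invalid_state")
  }
  n <- max(length(marker), length(rating))
  step <- ifelse(rep_len(rating, n) == 1, 1, -1)
  pmin(pmax(rep_len(marker, n) + step, .MARKER_MIN), .MARKER_MAX)
}
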