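#' Agent parameters for the synthetic participant
#'
#' Bundles the generative parameters of a simulated participant: the
#' delta-rule learning rate and softmax inverse temperature of the
#' performance-tracking model, plus context-signed self-other mergence (SOM)
#' weights that bias the rating decision variables. With both `w_som_*` at 0
#' (and `w_context_O = 0`) the agent is a pure appropriate-estimation agent
#' whose rating probabilities equal the fitted model's exactly.
#'
#' The SOM bias enters the decision variable, not the stored estimate: the
#' O-rating decision variable is
#' `O_performance + w_som_StoO * context * (S_performance - 8) - marker_O`,
#' and symmetrically for the S rating. `w_context_O` adds an optimism-style
#' context main effect (`+ w_context_O * context`) to the O-rating decision
#' variable only.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Inverse temperature, > 0.
#' @param w_som_StoO Context-signed weight of own performance on O ratings.
#' @param w_som_OtoS Context-signed weight of the other's performance on S
#'   ratings.
#' @param w_context_O Context main-effect bias on O ratings
#'   (performance-scale points).
#' @param p_false_start Per-trial probability of a self false start.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.3, beta = 0.8, w_som_StoO = 0,
                         w_som_OtoS = 0, w_context_O = 0,
                         p_false_start = 0) {
  if (alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].", class = "somtrack_invalid_parameter")
  }
  if (beta <= 0) {
    abort("`beta` must be positive.", class = "somtrack_invalid_parameter")
  }
  structure(list(alpha = alpha, beta = beta, w_som_StoO = w_som_StoO,
                 w_som_OtoS = w_som_OtoS, w_context_O = w_context_O,
                 p_false_start = p_false_start),
            class = "agent_params")
}

#' Simulate one participant-session
#'
#' Plays a fully scheduled session with a synthetic agent that tracks all six
#' player-by-minigame performance levels with the delta rule, rates via the
#' softmax of a (possibly SOM-biased) decision variable, chooses
#' engage/avoid via the softmax of the model's engage expected value, and
#' drives the rating-marker staircase. When the main phase begins the
#' agent's estimates are re-anchored at the last starter feedback of each
#' player/minigame -- the same initialisation the fitted model uses -- so a
#' zero-SOM agent is exactly the model it will be fitted with.
#'
#' @param schedule A trial table with feedback and thresholds filled.
#' @param params An [agent_params()] object.
#' @param seed Integer seed; the record is a pure function of schedule,
#'   params and seed.
#' @return The schedule with behavior columns appended: `rating_S`,
#'   `rating_O` (1 = positive), `marker_S`, `marker_O` (values in force when
#'   the ratings were made), `choice`, `payoff_decision`, `bonus_S`,
#'   `bonus_O`, `payoff` (trial total), and the generating probabilities
#'   `p_rating_S`, `p_rating_O`, `p_engage_sim`.
#' @export
simulate_participant <- function(schedule, params, seed) {
  if (anyNA(schedule$threshold) || anyNA(schedule$feedback_S)) {
    abort("Schedule must have feedback and thresholds filled.",
          class = "somtrack_invalid_input")
  }
  stopifnot(inherits(params, "agent_params") || is.list(params))
  n <- nrow(schedule)
  est <- matrix(NA_real_, 3, 2, dimnames = list(.players, .minigames))
  markers <- matrix(7.5, 3, 2, dimnames = list(.players, .minigames))

  out <- tibble::tibble(
    rating_S = NA_integer_, rating_O = NA_integer_,
    marker_S = NA_real_, marker_O = NA_real_,
    choice = NA_character_, payoff_decision = NA_real_,
    bonus_S = NA_real_, bonus_O = NA_real_, payoff = NA_real_,
    p_rating_S = NA_real_, p_rating_O = NA_real_, p_engage_sim = NA_real_,
    .rows = n
  )
  fs <- schedule$false_start
  anchored <- FALSE

  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      mg <- schedule$minigame[i]
      if (schedule$phase[i] == "main" && !anchored) {
        # Re-anchor at the last starter feedback, as the model assumes.
        st <- schedule[schedule$phase == "starter", ]
        for (m in .minigames) {
          rows <- which(st$minigame == m)
          if (length(rows) == 0) next
          est["S", m] <- {
            ok <- rows[!fs[rows]]
            if (length(ok) > 0) st$feedback_S[tail(ok, 1)] else est["S", m]
          }
          est["O1", m] <- st$feedback_O1[tail(rows, 1)]
          est["O2", m] <- st$feedback_O2[tail(rows, 1)]
        }
        anchored <- TRUE
      }

      o <- schedule$relevant_other[i]
      ctx <- schedule$context[i]
      fb_o <- if (o == "O1") schedule$feedback_O1[i] else schedule$feedback_O2[i]

      if (params$p_false_start > 0 && schedule$phase[i] == "main") {
        fs[i] <- runif(1) < params$p_false_start
      }

      if (schedule$has_decisions[i]) {
        Sp <- if (is.na(est["S", mg])) .SCALE_MID else est["S", mg]
        Op <- if (is.na(est[o, mg])) .SCALE_MID else est[o, mg]
        m_S <- markers["S", mg]
        m_O <- markers[o, mg]
        dv_S <- Sp + params$w_som_OtoS * ctx * (Op - .SCALE_MID) - m_S
        dv_O <- Op + params$w_som_StoO * ctx * (Sp - .SCALE_MID) +
          params$w_context_O * ctx - m_O
        p_S <- plogis(params$beta * dv_S)
        p_O <- plogis(params$beta * dv_O)
        r_S <- as.integer(runif(1) < p_S)
        r_O <- as.integer(runif(1) < p_O)
        ev <- ev_engage(Sp, Op, schedule$threshold[i], ctx)
        p_e <- plogis(params$beta * ev)
        ch <- if (runif(1) < p_e) "engage" else "avoid"

        pay_dec <- settle_trial(ch, schedule$feedback_S[i], fb_o,
                                schedule$threshold[i], ctx,
                                false_start = fs[i], u = runif(1))
        if (fs[i]) {
          b_S <- 0; b_O <- 0
        } else {
          b_S <- if (r_S == 1) {
            if (schedule$feedback_S[i] > m_S) 0.25 else -0.25
          } else 0
          b_O <- if (r_O == 1) (if (fb_o > m_O) 0.25 else -0.25) else 0
        }
        out$rating_S[i] <- r_S; out$rating_O[i] <- r_O
        out$marker_S[i] <- m_S; out$marker_O[i] <- m_O
        out$choice[i] <- ch
        out$payoff_decision[i] <- pay_dec
        out$bonus_S[i] <- b_S; out$bonus_O[i] <- b_O
        out$payoff[i] <- if (fs[i]) -3 else pay_dec + b_S + b_O
        out$p_rating_S[i] <- p_S; out$p_rating_O[i] <- p_O
        out$p_engage_sim[i] <- p_e

        markers["S", mg] <- update_rating_marker(m_S, r_S)
        markers[o, mg] <- update_rating_marker(m_O, r_O)
      }

      # Learn from this trial's feedback (self skipped on false starts).
      if (!fs[i]) {
        est["S", mg] <- if (is.na(est["S", mg])) schedule$feedback_S[i] else
          update_performance(est["S", mg], schedule$feedback_S[i], params$alpha)
      }
      est["O1", mg] <- if (is.na(est["O1", mg])) schedule$feedback_O1[i] else
        update_performance(est["O1", mg], schedule$feedback_O1[i], params$alpha)
      est["O2", mg] <- if (is.na(est["O2", mg])) schedule$feedback_O2[i] else
        update_performance(est["O2", mg], schedule$feedback_O2[i], params$alpha)
    }
  })

  res <- dplyr::bind_cols(schedule, out)
  res$false_start <- fs
  res
}

#' Simulate a two-group, two-session cohort
#'
#' Emulates the stimulation study design: two groups (`dmPFC`, `vertex`) of
#' `n_per_group` participants, each playing two sessions with the identical
#' feedback schedule -- one under `cTBS`, one under `no-cTBS`, order
#' counterbalanced across participants. The stimulation effect is injected as
#' an additive shift `ctbs_som_delta` of `w_som_StoO` applied only in
#' dmPFC x cTBS sessions. Per-participant parameters are drawn from
#' truncated normal populations.
#'
#' @param n_per_group Participants per group (>= 2).
#' @param seed Master seed; everything downstream is derived from it.
#' @param ctbs_som_delta Additive shift of `w_som_StoO` in dmPFC cTBS
#'   sessions (the manipulable stimulation effect; 0 = sham).
#' @param alpha_mean,alpha_sd,beta_mean,beta_sd Population moments of the
#'   learning rate (truncated to \[0.02, 0.98\]) and inverse temperature
#'   (truncated to \[0.05, 5\]).
#' @param w_som_StoO_mean,w_som_StoO_sd,w_som_OtoS_mean,w_som_OtoS_sd
#'   Population moments of the two SOM weights (truncated to \[-1, 1\]).
#' @param w_context_O Context main-effect bias on O ratings, shared by all
#'   agents (optimism-style; points).
#' @param p_false_start Per-trial self false-start probability.
#' @param n_main,n_starter Session lengths (see [generate_schedule()]).
#' @param shared_schedule If `TRUE` (default) one feedback/threshold
#'   schedule is shared by all participants, as in the task, where schedules
#'   were pre-determined and matched across participants; if `FALSE` each
#'   participant receives an independent schedule (still identical across
#'   their own two sessions).
#' @param drift_sd,obs_sd,threshold_sd Schedule generator parameters.
#' @return A list of class `som_cohort` with elements `trials` (all session
#'   records stacked, with `participant`, `group`, `condition`, `session`
#'   columns) and `manifest` (one row per participant with group, session
#'   order and true generating parameters).
#' @examples
#' \donttest{
#' coh <- simulate_cohort(n_per_group = 3, seed = 42, n_main = 24, n_starter = 8)
#' coh$manifest
#' }
#' @export
simulate_cohort <- function(n_per_group = 28, seed = 1, ctbs_som_delta = 0,
                            alpha_mean = 0.3, alpha_sd = 0.1,
                            beta_mean = 0.8, beta_sd = 0.2,
                            w_som_StoO_mean = 0.15, w_som_StoO_sd = 0.1,
                            w_som_OtoS_mean = 0.10, w_som_OtoS_sd = 0.1,
                            w_context_O = 0.5, p_false_start = 0,
                            n_main = 88L, n_starter = 16L,
                            shared_schedule = TRUE,
                            drift_sd = 0.35, obs_sd = 1.2, threshold_sd = 2) {
  if (n_per_group < 2) {
    abort("`n_per_group` must be at least 2.",
          class = "somtrack_invalid_input")
  }
  n_tot <- 2L * n_per_group
  seeds <- derive_seeds(seed, 3L + 3L * n_tot)
  groups <- rep(c("dmPFC", "vertex"), each = n_per_group)

  draws <- withr::with_seed(seeds[1], tibble::tibble(
    alpha = rtnorm(n_tot, alpha_mean, alpha_sd, 0.02, 0.98),
    beta = rtnorm(n_tot, beta_mean, beta_sd, 0.05, 5),
    w_som_StoO = rtnorm(n_tot, w_som_StoO_mean, w_som_StoO_sd, -1, 1),
    w_som_OtoS = rtnorm(n_tot, w_som_OtoS_mean, w_som_OtoS_sd, -1, 1)
  ))

  make_schedule <- function(s) {
    sch <- generate_schedule(s, n_main = n_main, n_starter = n_starter)
    sch <- generate_feedback_schedule(sch, seed = s + 1L,
                                      drift_sd = drift_sd, obs_sd = obs_sd)
    generate_thresholds(sch, seed = s + 2L, noise_sd = threshold_sd)
  }
  shared <- if (shared_schedule) make_schedule(seeds[2]) else NULL

  conditions <- c("cTBS", "no-cTBS")
  records <- vector("list", 2L * n_tot)
  manifest <- vector("list", n_tot)
  for (p in seq_len(n_tot)) {
    pid <- sprintf("P%02d", p)
    grp <- groups[p]
    # Counterbalance session order within each group.
    first_ctbs <- (p %% 2L) == 1L
    order_p <- if (first_ctbs) conditions else rev(conditions)
    sch <- if (shared_schedule) shared else make_schedule(seeds[3L + 3L * (p - 1L)])
    for (s in 1:2) {
      cond <- order_p[s]
      w_sto <- draws$w_som_StoO[p] +
        if (grp == "dmPFC" && cond == "cTBS") ctbs_som_delta else 0
      par <- agent_params(alpha = draws$alpha[p], beta = draws$beta[p],
                          w_som_StoO = w_sto,
                          w_som_OtoS = draws$w_som_OtoS[p],
                          w_context_O = w_context_O,
                          p_false_start = p_false_start)
      sid <- paste(pid, cond, sep = "_")
      rec <- simulate_participant(
        dplyr::mutate(sch, session_id = sid),
        par, seed = seeds[3L + 3L * (p - 1L) + s]
      )
      rec <- dplyr::mutate(rec, participant = pid, group = grp,
                           condition = cond, session = s, .before = 1)
      records[[2L * (p - 1L) + s]] <- rec
    }
    manifest[[p]] <- tibble::tibble(
      participant = pid, group = grp,
      session1_condition = order_p[1],
      alpha = draws$alpha[p], beta = draws$beta[p],
      w_som_StoO = draws$w_som_StoO[p], w_som_OtoS = draws$w_som_OtoS[p],
      w_context_O = w_context_O, ctbs_som_delta = ctbs_som_delta
    )
  }
  structure(
    list(trials = dplyr::bind_rows(records),
         manifest = dplyr::bind_rows(manifest)),
    class = "som_cohort"
  )
}

#' @export
print.som_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d participants (%s), %d session records\n",
              nrow(x$manifest),
              paste(table(x$manifest$group), collapse = " + "),
              length(unique(paste(x$trials$participant, x$trials$condition)))))
  invisible(x)
}
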