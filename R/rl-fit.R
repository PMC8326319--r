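# Latent-pass machinery shared by session_nll(), trace_latents() and
# fit_group(). A session record is preprocessed once into index structures;
# the alpha-dependent recency-weighted estimates are then computed with the
# linear recursive filter perf_{k+1} = (1 - alpha) perf_k + alpha f_k.

required_record_cols <- c(
  "trial_index", "phase", "minigame", "context", "relevant_other",
  "threshold", "feedback_S", "feedback_O1", "feedback_O2", "false_start",
  "has_decisions"
)

behavior_cols <- c("rating_S", "rating_O", "marker_S", "marker_O",
                   "choice", "payoff")

prepare_session <- function(record, require_behavior = TRUE) {
  need <- required_record_cols
  if (require_behavior) need <- c(need, behavior_cols)
  missing <- setdiff(need, names(record))
  if (length(missing) > 0) {
    abort(paste0("Session record lacks columns: ",
                 paste(missing, collapse = ", ")),
          class = "somtrack_invalid_input")
  }
  if (anyNA(record$threshold)) {
    abort("Session record has missing thresholds (run generate_thresholds()).",
          class = "somtrack_invalid_input")
  }
  record <- dplyr::arrange(record, .data$trial_index)
  starter <- record[record$phase == "starter", ]
  main <- record[record$phase == "main", ]
  if (nrow(main) == 0) {
    abort("Session record has no main-phase trials.",
          class = "somtrack_invalid_input")
  }

  fb <- list(S = main$feedback_S, O1 = main$feedback_O1, O2 = main$feedback_O2)
  series <- list()
  warned <- FALSE
  for (mg in .minigames) {
    rows_mg <- which(main$minigame == mg)
    for (pl in .players) {
      key <- paste(pl, mg, sep = ".")
      upd <- rows_mg
      if (pl == "S") upd <- rows_mg[!main$false_start[rows_mg]]
      st_fb <- starter[[paste0("feedback_", pl)]][starter$minigame == mg]
      if (pl == "S") {
        st_ok <- !starter$false_start[starter$minigame == mg]
        st_fb <- st_fb[st_ok]
      }
      if (length(st_fb) > 0 && !is.na(tail(st_fb, 1))) {
        init <- as.numeric(tail(st_fb, 1))
      } else {
        if (!warned) {
          warn(paste("No starter-session feedback available;",
                     "initializing estimates at the first main-phase",
                     "feedback of each player/minigame."))
          warned <- TRUE
        }
        init <- if (length(upd) > 0) as.numeric(fb[[pl]][upd[1]]) else .SCALE_MID
      }
      series[[key]] <- list(pl = pl, mg = mg, upd = upd, init = init,
                            f = as.numeric(fb[[pl]][upd]),
                            rows_mg = rows_mg)
    }
  }
  list(main = main, series = series)
}

# Per-trial pre-decision estimates and PEs for one alpha.
latents_for_alpha <- function(prep, alpha) {
  main <- prep$main
  n <- nrow(main)
  est <- matrix(NA_real_, nrow = n, ncol = 3, dimnames = list(NULL, .players))
  for (s in prep$series) {
    if (length(s$rows_mg) == 0) next
    if (length(s$f) > 0) {
      filtered <- as.numeric(stats::filter(alpha * s$f, 1 - alpha,
                                           method = "recursive", init = s$init))
      est_seq <- c(s$init, filtered)  # est_seq[k + 1] = estimate after k updates
    } else {
      est_seq <- s$init
    }
    k_before <- findInterval(s$rows_mg - 0.5, s$upd)
    est[s$rows_mg, s$pl] <- est_seq[k_before + 1]
  }
  fo <- ifelse(main$relevant_other == "O1", main$feedback_O1, main$feedback_O2)
  O_perf <- ifelse(main$relevant_other == "O1", est[, "O1"], est[, "O2"])
  list(
    S_performance = est[, "S"],
    O_performance = O_perf,
    PE_S = ifelse(main$false_start, NA_real_, main$feedback_S - est[, "S"]),
    PE_O = fo - O_perf
  )
}

#' Negative log-likelihood of one session under the performance-tracking model
#'
#' Runs the full latent pass (estimates initialised at the last starter
#' feedback of each player and minigame, delta-rule updates with `alpha`,
#' self never updated on false starts) and accumulates `-log p` over every S
#' rating, O rating and engage/avoid choice of the main-phase decision
#' trials -- three equally weighted likelihood terms per trial. Probabilities
#' are floored at 1e-10 so the result is always finite.
#'
#' @param record One session's trial table including behavior columns
#'   (`rating_S`, `rating_O`, `marker_S`, `marker_O`, `choice`, `payoff`).
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Inverse temperature, > 0.
#' @return The scalar negative log-likelihood.
#' @export
session_nll <- function(record, alpha, beta) {
  if (alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].", class = "somtrack_invalid_parameter")
  }
  if (beta <= 0) {
    abort("`beta` must be positive.", class = "somtrack_invalid_parameter")
  }
  prep <- prepare_session(record)
  nll_from_prep(prep, alpha, beta)
}

nll_from_prep <- function(prep, alpha, beta, lat = NULL) {
  main <- prep$main
  if (is.null(lat)) lat <- latents_for_alpha(prep, alpha)
  dec <- which(main$has_decisions)
  p_S <- plogis(beta * (lat$S_performance[dec] - main$marker_S[dec]))
  p_O <- plogis(beta * (lat$O_performance[dec] - main$marker_O[dec]))
  ev <- ev_engage(lat$S_performance[dec], lat$O_performance[dec],
                  main$threshold[dec], main$context[dec])
  p_e <- plogis(beta * ev)
  obs <- c(
    ifelse(main$rating_S[dec] == 1, p_S, 1 - p_S),
    ifelse(main$rating_O[dec] == 1, p_O, 1 - p_O),
    ifelse(main$choice[dec] == "engage", p_e, 1 - p_e)
  )
  -sum(log(pmax(obs, .P_FLOOR)))
}

#' Trial-wise latent model quantities for one session
#'
#' Replays the fitted model over a session and emits, for every main-phase
#' trial, the pre-decision performance estimates for self and the relevant
#' other, the feedback prediction errors (no self PE on false starts), the
#' rating and engage expected values, choice probability, total chosen
#' expected value and reward prediction error. These are the model-derived
#' regressors consumed by the rating GLMs.
#'
#' @inheritParams session_nll
#' @return A tibble with one row per main-phase trial: `trial_index`,
#'   `S_performance`, `O_performance`, `PE_S`, `PE_O`, `p_pos_S`, `p_pos_O`,
#'   `EV_S_rating`, `EV_O_rating`, `EV_engage`, `p_engage`, `EV_EAD`,
#'   `EV_chosen`, `RPE`.
#' @export
trace_latents <- function(record, alpha, beta) {
  prep <- prepare_session(record)
  main <- prep$main
  lat <- latents_for_alpha(prep, alpha)
  p_pos_S <- plogis(beta * (lat$S_performance - main$marker_S))
  p_pos_O <- plogis(beta * (lat$O_performance - main$marker_O))
  ev_e <- ev_engage(lat$S_performance, lat$O_performance,
                    main$threshold, main$context)
  evr_S <- ev_rating(p_pos_S, main$rating_S)
  evr_O <- ev_rating(p_pos_O, main$rating_O)
  ev_ead <- ifelse(!is.na(main$choice) & main$choice == "engage", ev_e, 0)
  tot <- ev_chosen_and_rpe(evr_S, evr_O, ev_ead, main$payoff)
  tibble::tibble(
    trial_index = main$trial_index,
    S_performance = lat$S_performance,
    O_performance = lat$O_performance,
    PE_S = lat$PE_S,
    PE_O = lat$PE_O,
    p_pos_S = p_pos_S,
    p_pos_O = p_pos_O,
    EV_S_rating = evr_S,
    EV_O_rating = evr_O,
    EV_engage = ev_e,
    p_engage = plogis(beta * ev_e),
    EV_EAD = ev_ead,
    EV_chosen = tot$EV_chosen,
    RPE = tot$RPE
  )
}

split_sessions <- function(trials) {
  keys <- intersect(c("participant", "group", "condition", "session",
                      "session_id"), names(trials))
  if (length(keys) == 0) {
    abort("Trial table has no session-identifying columns.",
          class = "somtrack_invalid_input")
  }
  split(trials, interaction(trials[keys], drop = TRUE, lex.order = TRUE))
}

#' Fit one group-level parameter set by maximum likelihood
#'
#' Minimises the summed [session_nll()] over all supplied sessions (all
#' participants, both sessions of one group, fitted together so that one
#' `(alpha, beta)` pair describes the group). Optimisation is bounded
#' quasi-Newton (`L-BFGS-B`) restarted from a fixed 5 x 5 grid of starting
#' values, so the fit is deterministic given its inputs.
#'
#' @param trials Trial table containing one or more sessions (rows of all
#'   sessions stacked; sessions are identified by the `participant`,
#'   `condition`, `session` and/or `session_id` columns).
#' @param beta_max Upper bound for the inverse temperature (default 20).
#' @param starts Optional 2-column matrix of (alpha, beta) starting values;
#'   defaults to the fixed 5 x 5 grid.
#' @return An object of class `som_fit`: a list with elements `alpha`,
#'   `beta`, `nll`, `n_sessions`, `n_decisions` and a `starts` tibble with
#'   the per-start solutions. Has [tidy()], [glance()] and `print` methods.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(n_per_group = 2, seed = 1, n_main = 24, n_starter = 8)
#' fit <- fit_group(dplyr::filter(coh$trials, group == "dmPFC"))
#' tidy(fit)
#' }
#' @export
fit_group <- function(trials, beta_max = 20, starts = NULL) {
  sessions <- split_sessions(trials)
  if (length(sessions) < 1) {
    abort("At least one session is required.", class = "somtrack_invalid_input")
  }
  preps <- lapply(sessions, prepare_session)

  cache <- new.env(parent = emptyenv())
  cache$alpha <- NA_real_
  cache$lats <- NULL
  total_nll <- function(par) {
    a <- par[1]; b <- par[2]
    if (is.na(a) || is.na(b) || a < 0 || a > 1 || b <= 0) return(1e10)
    if (!identical(a, cache$alpha)) {
      cache$lats <- lapply(preps, latents_for_alpha, alpha = a)
      cache$alpha <- a
    }
    sum(vapply(seq_along(preps), function(i) {
      nll_from_prep(preps[[i]], a, b, lat = cache$lats[[i]])
    }, numeric(1)))
  }

  if (is.null(starts)) {
    starts <- as.matrix(expand.grid(
      alpha = seq(0.1, 0.9, length.out = 5),
      beta = c(0.1, 0.3, 0.8, 2, 5)
    ))
  }
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    res <- tryCatch(
      optim(starts[i, ], total_nll, method = "L-BFGS-B",
            lower = c(0, 1e-3), upper = c(1, beta_max)),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    tibble::tibble(start_alpha = unname(starts[i, 1]),
                   start_beta = unname(starts[i, 2]),
                   alpha = unname(res$par[1]), beta = unname(res$par[2]),
                   nll = res$value, convergence = res$convergence)
  })
  runs <- dplyr::bind_rows(runs)
  ok <- runs[runs$convergence == 0, ]
  if (nrow(ok) == 0) {
    abort("Optimizer failed to converge from every starting value.",
          class = "somtrack_fitting_error")
  }
  best <- ok[which.min(ok$nll), ]
  n_dec <- sum(vapply(preps, function(p) sum(p$main$has_decisions), numeric(1)))
  structure(
    list(alpha = best$alpha, beta = best$beta, nll = best$nll,
         n_sessions = length(preps), n_decisions = 3L * n_dec,
         starts = runs),
    class = "som_fit"
  )
}

#' @export
print.som_fit <- function(x, ...) {
  cat("Group-level performance-tracking model fit\n")
  cat(sprintf("  alpha = %.4f, beta = %.4f\n", x$alpha, x$beta))
  cat(sprintf("  nLL = %.3f over %d sessions (%d likelihood terms)\n",
              x$nll, x$n_sessions, x$n_decisions))
  invisible(x)
}

#' @rdname fit_group
#' @param x A `som_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.som_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = c(x$alpha, x$beta))
}

#' @rdname fit_group
#' @exportS3Method generics::glance
glance.som_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta, nll = x$nll,
                 n_sessions = x$n_sessions, n_decisions = x$n_decisions)
}
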