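#' Delta-rule update of a performance estimate
#'
#' `perf + alpha * (feedback - perf)`: the Rescorla-Wagner update applied to
#' the player- and minigame-specific performance estimate. For self on
#' false-start trials the update is skipped entirely by the callers (the
#' estimate is carried forward unchanged and no prediction error is logged).
#'
#' @param perf Current estimate.
#' @param feedback Observed performance feedback.
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated estimate (vectorised).
#' @examples
#' update_performance(5, 9, 0.5)  # 7, prediction error 4
#' @export
update_performance <- function(perf, feedback, alpha) {
  if (any(alpha < 0 | alpha > 1)) {
    abort("`alpha` must lie in [0, 1].", class = "somtrack_invalid_parameter")
  }
  perf + alpha * (feedback - perf)
}

#' Probability of a positive rating
#'
#' Softmax (logistic) of `beta * (perf - marker)`: the probability that the
#' participant rates the player's upcoming performance above the rating
#' marker. Overflow-safe via [stats::plogis()].
#'
#' @param perf Performance estimate for the rated player.
#' @param marker Current rating-marker position.
#' @param beta Inverse temperature, > 0.
#' @return Probability in (0, 1), strictly increasing in `perf`.
#' @export
p_positive_rating <- function(perf, marker, beta) {
  if (any(beta <= 0)) {
    abort("`beta` must be positive.", class = "somtrack_invalid_parameter")
  }
  plogis(beta * (perf - marker))
}

#' Expected value of a rating
#'
#' Positive ratings are worth `(p_pos - 0.5) * 2 * bonus`, spanning
#' \[-bonus, +bonus\]; negative ratings never pay and have expected value 0.
#'
#' @param p_pos Probability that the rated performance exceeds the marker.
#' @param rating 1 (positive) or 0 (negative); `"positive"`/`"negative"`
#'   also accepted.
#' @param bonus Points at stake for a positive rating (default 0.25).
#' @return Expected value (vectorised).
#' @export
ev_rating <- function(p_pos, rating, bonus = 0.25) {
  if (is.character(rating)) rating <- as.integer(rating == "positive")
  n <- max(length(p_pos), length(rating))
  ifelse(rep_len(rating, n) == 1, (rep_len(p_pos, n) - 0.5) * 2 * bonus, 0)
}

#' Expected value of engaging
#'
#' Competition: `S_perf - O_perf - threshold`; cooperation:
#' `(S_perf + O_perf) / 2 - threshold`. The model analogue of
#' [engage_payoff()] with performance estimates in place of realised
#' feedback.
#'
#' @param S_perf,O_perf Performance estimates for self and relevant other.
#' @param threshold Trial threshold.
#' @param context +1 cooperation, -1 competition.
#' @return Expected value (vectorised).
#' @export
ev_engage <- function(S_perf, O_perf, threshold, context) {
  n <- max(length(S_perf), length(O_perf), length(threshold),
           length(context))
  context <- rep_len(context, n)
  ifelse(context < 0,
         S_perf - O_perf - threshold,
         (S_perf + O_perf) / 2 - threshold)
}

#' Probability of engaging
#'
#' Softmax over engaging (value `ev`) versus avoiding (value fixed at 0):
#' the logistic of `beta * ev`, overflow-safe.
#'
#' @param ev Expected value of engaging.
#' @param beta Inverse temperature, > 0.
#' @return Probability in (0, 1).
#' @export
p_engage <- function(ev, beta) {
  if (any(beta <= 0)) {
    abort("`beta` must be positive.", class = "somtrack_invalid_parameter")
  }
  plogis(beta * ev)
}

#' Total chosen expected value and reward prediction error
#'
#' The trial's full reward expectation is the sum of both rating EVs and the
#' EV of the engage/avoid choice actually taken (0 for avoid); the reward
#' prediction error is the realised total payoff minus that expectation.
#'
#' @param ev_S_rating,ev_O_rating Expected values of the S and O ratings.
#' @param ev_ead Expected value of the chosen engage/avoid action
#'   (`ev_engage` if engaged, 0 if avoided).
#' @param reward Realised total payoff of the trial (choice outcome plus
#'   rating bonuses).
#' @return A tibble with columns `EV_chosen` and `RPE`.
#' @export
ev_chosen_and_rpe <- function(ev_S_rating, ev_O_rating, ev_ead, reward) {
  ev_chosen <- ev_S_rating + ev_O_rating + ev_ead
  tibble::tibble(EV_chosen = ev_chosen, RPE = reward - ev_chosen)
}
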