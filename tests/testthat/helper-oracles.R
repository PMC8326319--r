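# Independent oracle implementations used only by the tests. Written as
# plain straight-line code, sharing nothing with the package internals.

# Negative log-likelihood of one session, re-derived step by step: explicit
# softmax, explicit per-player/minigame estimate bookkeeping, explicit
# last-starter-feedback initialization, explicit false-start skipping.
oracle_session_nll <- function(record, alpha, beta) {
  record <- record[order(record$trial_index), ]
  starter <- record[record$phase == "starter", ]
  main <- record[record$phase == "main", ]
  est <- list()
  for (pl in c("S", "O1", "O2")) {
    for (mg in c("game1", "game2")) {
      st <- starter[starter$minigame == mg, ]
      if (pl == "S") st <- st[!st$false_start, ]
      fbcol <- paste0("feedback_", pl)
      est[[paste(pl, mg)]] <- st[[fbcol]][nrow(st)]
    }
  }
  nll <- 0
  for (i in seq_len(nrow(main))) {
    mg <- main$minigame[i]
    o <- main$relevant_other[i]
    Sp <- est[[paste("S", mg)]]
    Op <- est[[paste(o, mg)]]
    if (main$has_decisions[i]) {
      p_S <- exp(beta * (Sp - main$marker_S[i])) /
        (exp(beta * (Sp - main$marker_S[i])) + 1)
      p_O <- exp(beta * (Op - main$marker_O[i])) /
        (exp(beta * (Op - main$marker_O[i])) + 1)
      if (main$context[i] == -1) {
        ev <- Sp - Op - main$threshold[i]
      } else {
        ev <- (Sp + Op) / 2 - main$threshold[i]
      }
      p_e <- exp(beta * ev) / (exp(beta * ev) + exp(beta * 0))
      probs <- c(
        if (main$rating_S[i] == 1) p_S else 1 - p_S,
        if (main$rating_O[i] == 1) p_O else 1 - p_O,
        if (main$choice[i] == "engage") p_e else 1 - p_e
      )
      nll <- nll - sum(log(pmax(probs, 1e-10)))
    }
    if (!main$false_start[i]) {
      est[[paste("S", mg)]] <- est[[paste("S", mg)]] +
        alpha * (main$feedback_S[i] - est[[paste("S", mg)]])
    }
    est[[paste("O1", mg)]] <- est[[paste("O1", mg)]] +
      alpha * (main$feedback_O1[i] - est[[paste("O1", mg)]])
    est[[paste("O2", mg)]] <- est[[paste("O2", mg)]] +
      alpha * (main$feedback_O2[i] - est[[paste("O2", mg)]])
  }
  nll
}

# Logistic regression by hand-rolled iteratively reweighted least squares.
oracle_irls_logistic <- function(X, y, maxit = 200, tol = 1e-12) {
  X <- cbind(1, as.matrix(X))
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    b_new <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
    if (max(abs(b_new - b)) < tol) {
      b <- drop(b_new)
      break
    }
    b <- drop(b_new)
  }
  b
}

# Mixed-design (one between, one within factor) interaction F from full
# sums-of-squares decomposition of the within-participant stratum.
oracle_mixed_interaction_F <- function(participant, group, condition, value) {
  d <- data.frame(participant, group, condition, value)
  grand <- mean(d$value)
  subj_mean <- tapply(d$value, d$participant, mean)
  cond_mean <- tapply(d$value, d$condition, mean)
  cell_mean <- tapply(d$value, list(d$group, d$condition), mean)
  grp_mean <- tapply(d$value, d$group, mean)
  n_per_cell <- table(d$group, d$condition)
  # SS condition
  n_cond <- table(d$condition)
  ss_cond <- sum(n_cond * (cond_mean - grand)^2)
  # SS interaction
  ss_int <- 0
  for (g in rownames(cell_mean)) {
    for (cc in colnames(cell_mean)) {
      ss_int <- ss_int + n_per_cell[g, cc] *
        (cell_mean[g, cc] - grp_mean[g] - cond_mean[cc] + grand)^2
    }
  }
  # Within-participant residual: total within-subject SS minus condition
  # and interaction components.
  ss_within <- sum((d$value - subj_mean[as.character(d$participant)])^2)
  ss_res <- ss_within - ss_cond - ss_int
  n_subj <- length(unique(d$participant))
  n_grp <- length(unique(d$group))
  n_cnd <- length(unique(d$condition))
  df_int <- (n_grp - 1) * (n_cnd - 1)
  df_res <- (n_subj - n_grp) * (n_cnd - 1)
  unname((ss_int / df_int) / (ss_res / df_res))
}
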