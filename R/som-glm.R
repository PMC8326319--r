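# Rating GLMs quantifying self-other mergence: per participant-session
# logistic regressions of the binary ability ratings on model-derived
# performance estimates, with SOM measured as performance x context
# interaction coefficients.

zscore <- function(x, label) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) {
    abort(sprintf("Regressor `%s` has zero variance over included trials.",
                  label),
          class = "somtrack_degenerate_design")
  }
  (x - mean(x)) / s
}

#' Assemble a rating-GLM design matrix for one session
#'
#' Joins the latent trace to the behavioral record, restricts to engage
#' trials (only there is the social context consequential), and builds the
#' regressor set of the requested model variant. The interaction model
#' (`"GLM2"`) uses `S_performance`, `O_performance`, their interactions with
#' context (computed as z-scored performance times z-scored context, then
#' re-standardised), `context`, and the rated player's marker; the binned
#' variants (`"GLM1-coop"`, `"GLM1-comp"`) keep only the performance and
#' marker regressors within one context. All columns are z-scored over the
#' included trials.
#'
#' @param trace Output of [trace_latents()] for the session.
#' @param record The session's trial table (with behavior columns).
#' @param target `"S"` or `"O"`: which rating is modelled.
#' @param variant `"GLM2"`, `"GLM1-coop"` or `"GLM1-comp"`.
#' @return A list of class `som_design` with elements `X` (tibble of
#'   z-scored regressors), `y` (binary outcome, 1 = positive rating),
#'   `n_trials`, `target`, `variant`.
#' @export
build_design <- function(trace, record, target = c("O", "S"),
                         variant = c("GLM2", "GLM1-coop", "GLM1-comp")) {
  target <- match.arg(target)
  variant <- match.arg(variant)
  d <- dplyr::inner_join(
    dplyr::select(trace, "trial_index", "S_performance", "O_performance"),
    dplyr::filter(record, .data$phase == "main", .data$has_decisions),
    by = "trial_index"
  )
  d <- dplyr::filter(d, !is.na(.data$choice), .data$choice == "engage")
  if (variant == "GLM1-coop") d <- dplyr::filter(d, .data$context > 0)
  if (variant == "GLM1-comp") d <- dplyr::filter(d, .data$context < 0)

  marker <- if (target == "S") d$marker_S else d$marker_O
  y <- if (target == "S") d$rating_S else d$rating_O

  if (variant == "GLM2") {
    ncols <- 6L
  } else {
    ncols <- 3L
  }
  if (nrow(d) < ncols + 2L) {
    abort(sprintf(
      "Only %d engage trials for a %d-regressor design (need at least %d).",
      nrow(d), ncols, ncols + 2L),
      class = "somtrack_underdetermined_design")
  }

  zS <- zscore(d$S_performance, "S_performance")
  zO <- zscore(d$O_performance, "O_performance")
  if (variant == "GLM2") {
    zC <- zscore(d$context, "context")
    X <- tibble::tibble(
      S_performance = zS,
      O_performance = zO,
      S_performance_x_context = zscore(zS * zC, "S_performance_x_context"),
      O_performance_x_context = zscore(zO * zC, "O_performance_x_context"),
      context = zC,
      marker = zscore(marker, "marker")
    )
  } else {
    X <- tibble::tibble(
      S_performance = zS,
      O_performance = zO,
      marker = zscore(marker, "marker")
    )
  }
  structure(list(X = X, y = as.integer(y), n_trials = nrow(d),
                 target = target, variant = variant),
            class = "som_design")
}

#' Fit a logistic rating GLM
#'
#' Maximum-likelihood logistic regression (with intercept) of the binary
#' rating on a [build_design()] regressor set. Alongside the raw
#' coefficients it returns variance-weighted effects (`vw_beta` =
#' coefficient / standard error, the coefficient's t statistic), used as a
#' noise-deweighted per-session effect size. Separation or non-convergence
#' is flagged rather than returning unstable estimates.
#'
#' @param design A `som_design` object.
#' @return A tibble of class `som_glm_result` with columns `term`, `beta`,
#'   `se`, `vw_beta`, and attributes `n_trials` and `converged`.
#' @export
fit_logistic <- function(design) {
  stopifnot(inherits(design, "som_design"))
  dat <- dplyr::bind_cols(tibble::tibble(.y = design$y), design$X)
  no_conv <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      # IRLS non-convergence invalidates the fit; the "fitted probabilities
      # 0 or 1" warning alone does not (near-saturated trials are normal
      # with strong performance signals) -- separation is caught instead by
      # the magnitude checks on the estimates and standard errors.
      if (grepl("did not converge", conditionMessage(w))) no_conv <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  converged <- isTRUE(fit$converged) && !no_conv &&
    all(is.finite(se)) && all(abs(est) < 15) && all(se < 25)
  out <- tibble::tibble(
    term = names(est), beta = unname(est), se = unname(se),
    vw_beta = unname(est / se)
  )
  structure(out, class = c("som_glm_result", class(out)),
            n_trials = design$n_trials, converged = converged)
}

normalize_params <- function(trials, params) {
  groups <- unique(trials$group %||% "all")
  lookup <- function(g) NULL
  if (inherits(params, "som_fit")) {
    lookup <- function(g) c(alpha = params$alpha, beta = params$beta)
  } else if (is.data.frame(params)) {
    lookup <- function(g) {
      row <- params[params$group == g, ]
      if (nrow(row) == 0) {
        abort(sprintf("No parameters supplied for group `%s`.", g),
              class = "somtrack_invalid_input")
      }
      c(alpha = row$alpha[1], beta = row$beta[1])
    }
  } else if (is.list(params) && all(vapply(params, inherits, TRUE, "som_fit"))) {
    lookup <- function(g) {
      f <- params[[g]]
      if (is.null(f)) {
        abort(sprintf("No fit supplied for group `%s`.", g),
              class = "somtrack_invalid_input")
      }
      c(alpha = f$alpha, beta = f$beta)
    }
  } else if (is.list(params) && !is.null(params$alpha)) {
    lookup <- function(g) c(alpha = params$alpha, beta = params$beta)
  } else {
    abort("`params` must be a som_fit, a named list of som_fits, a tibble with group/alpha/beta, or list(alpha=, beta=).",
          class = "somtrack_invalid_input")
  }
  lookup
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per participant-session SOM effect sizes
#'
#' Runs the latent pass and both interaction rating GLMs (S- and O-rating
#' models) on every session of a trial table and extracts the SOM
#' coefficients: `som_StoO` is the S-performance x context coefficient of
#' the O-rating model, `som_OtoS` the O-performance x context coefficient of
#' the S-rating model, each in raw (`_raw`) and variance-weighted (`_vw`)
#' flavors, together with the context main effects of both models. Sessions
#' whose GLM is underdetermined, degenerate or separated are flagged
#' (`converged = FALSE`, effects `NA`) and counted in a message.
#'
#' @param trials Trial table of one or more sessions (e.g.
#'   `simulate_cohort(...)$trials`).
#' @param params Group-level model parameters: a [fit_group()] result, a
#'   named list of them keyed by group, a tibble with `group`, `alpha`,
#'   `beta` columns, or `list(alpha =, beta =)`.
#' @param targets Which rating models to fit; the default fits both. Fitting
#'   only `"O"` halves the work when just `som_StoO` is needed.
#' @return A tibble of class `som_effects`, one row per participant-session.
#' @export
som_effects <- function(trials, params, targets = c("S", "O")) {
  lookup <- normalize_params(trials, params)
  sessions <- split_sessions(trials)
  n_flagged <- 0L
  rows <- lapply(sessions, function(rec) {
    g <- rec$group[1] %||% "all"
    th <- lookup(g)
    meta <- tibble::tibble(
      participant = rec$participant[1] %||% NA_character_,
      group = rec$group[1] %||% NA_character_,
      condition = rec$condition[1] %||% NA_character_,
      session = rec$session[1] %||% NA_integer_,
      session_id = rec$session_id[1]
    )
    res <- tryCatch({
      trace <- trace_latents(rec, th[["alpha"]], th[["beta"]])
      out <- list(som_StoO_raw = NA_real_, som_StoO_vw = NA_real_,
                  som_OtoS_raw = NA_real_, som_OtoS_vw = NA_real_,
                  context_S_raw = NA_real_, context_S_vw = NA_real_,
                  context_O_raw = NA_real_, context_O_vw = NA_real_)
      conv <- TRUE
      n_eng <- NA_integer_
      if ("O" %in% targets) {
        des_O <- build_design(trace, rec, target = "O", variant = "GLM2")
        fit_O <- fit_logistic(des_O)
        n_eng <- des_O$n_trials
        conv <- conv && attr(fit_O, "converged")
        i <- match("S_performance_x_context", fit_O$term)
        out$som_StoO_raw <- fit_O$beta[i]; out$som_StoO_vw <- fit_O$vw_beta[i]
        j <- match("context", fit_O$term)
        out$context_O_raw <- fit_O$beta[j]; out$context_O_vw <- fit_O$vw_beta[j]
      }
      if ("S" %in% targets) {
        des_S <- build_design(trace, rec, target = "S", variant = "GLM2")
        fit_S <- fit_logistic(des_S)
        n_eng <- des_S$n_trials
        conv <- conv && attr(fit_S, "converged")
        i <- match("O_performance_x_context", fit_S$term)
        out$som_OtoS_raw <- fit_S$beta[i]; out$som_OtoS_vw <- fit_S$vw_beta[i]
        j <- match("context", fit_S$term)
        out$context_S_raw <- fit_S$beta[j]; out$context_S_vw <- fit_S$vw_beta[j]
      }
      dplyr::bind_cols(meta, tibble::as_tibble(out),
                       tibble::tibble(n_engage = n_eng, converged = conv))
    }, error = function(e) {
      dplyr::bind_cols(meta, tibble::tibble(
        som_StoO_raw = NA_real_, som_StoO_vw = NA_real_,
        som_OtoS_raw = NA_real_, som_OtoS_vw = NA_real_,
        context_S_raw = NA_real_, context_S_vw = NA_real_,
        context_O_raw = NA_real_, context_O_vw = NA_real_,
        n_engage = NA_integer_, converged = FALSE))
    })
    if (!isTRUE(res$converged)) n_flagged <<- n_flagged + 1L
    res
  })
  out <- dplyr::bind_rows(rows)
  if (n_flagged > 0) {
    message(sprintf("%d of %d sessions flagged (separation/underdetermined); their effects are NA.",
                    n_flagged, length(sessions)))
  }
  structure(out, class = c("som_effects", class(out)))
}
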