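# Group-level inference on the per-session SOM effect sizes: baseline
# one-sample t tests (no-cTBS sessions pooled over groups) and the
# stimulation comparison (2 x 2 mixed-design ANOVA plus the within-dmPFC
# paired t test).

one_sample_row <- function(x, label) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (sd(x) < 1e-300) {
    # Constant data: t = 0 (p = 1) when centred on the null, otherwise
    # infinitely far from it.
    stat <- if (abs(mean(x)) < 1e-300) 0 else sign(mean(x)) * Inf
    return(tibble::tibble(
      test = label, estimate = mean(x), statistic = stat,
      df = n - 1, p.value = ifelse(stat == 0, 1, 0), n = n,
      direction = ifelse(mean(x) >= 0, "positive", "negative")))
  }
  tt <- t.test(x, mu = 0)
  tibble::tibble(
    test = label, estimate = unname(tt$estimate),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p.value = tt$p.value, n = n,
    direction = ifelse(unname(tt$estimate) >= 0, "positive", "negative")
  )
}

#' Baseline SOM and context tests on unstimulated sessions
#'
#' Pools the no-cTBS sessions of both groups and runs two-sided one-sample
#' t tests across participants on the variance-weighted SOM effects
#' (`som_OtoS_vw`, `som_StoO_vw`) and on the context main effects of the S-
#' and O-rating models (`context_S_vw`, `context_O_vw`). A positive SOM
#' effect means the inappropriate player's performance influences ratings
#' more positively in cooperation than in competition.
#'
#' @param effects A [som_effects()] table.
#' @param condition Label of the unstimulated condition (default
#'   `"no-cTBS"`; sessions with `NA` condition are treated as baseline).
#' @return A tibble with one row per test: `test`, `estimate`, `statistic`
#'   (t), `df`, `p.value`, `n`, `direction`.
#' @export
baseline_som_tests <- function(effects, condition = "no-cTBS") {
  base <- effects
  if (!all(is.na(effects$condition))) {
    base <- dplyr::filter(effects, .data$condition == !!condition)
  }
  base <- dplyr::filter(base, .data$converged)
  if (nrow(base) < 3) {
    abort("Fewer than 3 usable sessions for baseline tests.",
          class = "somtrack_insufficient_data")
  }
  dplyr::bind_rows(
    one_sample_row(base$som_OtoS_vw, "SOM_int(O->S)"),
    one_sample_row(base$som_StoO_vw, "SOM_int(S->O)"),
    one_sample_row(base$context_S_vw, "context main effect (S rating)"),
    one_sample_row(base$context_O_vw, "context main effect (O rating)")
  )
}

# Mixed-design interaction F from aov()'s within-participant stratum. On a
# 2 x 2 design this equals the squared pooled two-sample t on
# per-participant condition differences (asserted in the tests). Constant
# data (zero residual variance) is reported as F = 0.
mixed_anova_interaction <- function(df) {
  df$participant <- factor(df$participant)
  df$group <- factor(df$group)
  df$condition <- factor(df$condition)
  df1 <- (nlevels(df$group) - 1L) * (nlevels(df$condition) - 1L)
  df2 <- (nlevels(df$participant) - nlevels(df$group)) *
    (nlevels(df$condition) - 1L)
  if (stats::var(df$value) < 1e-24) {
    return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  }
  fit <- aov(value ~ group * condition + Error(participant / condition),
             data = df)
  tab <- summary(fit)[["Error: participant:condition"]][[1]]
  row <- grep("group:condition", rownames(tab))
  f <- tab[row, "F value"]
  p <- tab[row, "Pr(>F)"]
  if (!is.finite(f)) {
    f <- 0
    p <- 1
  }
  list(F = f, df1 = tab[row, "Df"], df2 = tab[nrow(tab), "Df"], p = p)
}

#' Stimulation-by-group test of the SOM effect
#'
#' The critical causal test: a 2 x 2 mixed-design ANOVA on the raw-beta
#' `som_StoO` effect with between-participant factor group (dmPFC/vertex)
#' and within-participant factor stimulation (cTBS/no-cTBS), plus paired
#' t tests (cTBS vs. no-cTBS) within each group. Participants lacking either
#' session (or with a flagged GLM) are dropped complete-case with a message.
#'
#' @param effects A [som_effects()] table with both sessions per
#'   participant.
#' @param measure Column to analyse (default `"som_StoO_raw"`; stimulation
#'   contrasts use standard rather than variance-weighted betas).
#' @return A tibble with rows for the group x stimulation interaction
#'   (F, df1, df2) and the per-group paired t tests.
#' @export
ctbs_interaction_test <- function(effects, measure = "som_StoO_raw") {
  d <- tibble::tibble(
    participant = effects$participant,
    group = effects$group,
    condition = effects$condition,
    value = effects[[measure]],
    converged = effects$converged
  )
  d <- dplyr::filter(d, .data$converged, is.finite(.data$value))
  counts <- dplyr::count(d, .data$participant)
  keep <- counts$participant[counts$n == 2]
  dropped <- dplyr::n_distinct(d$participant) - length(keep)
  if (dropped > 0) {
    message(sprintf("%d participant(s) dropped (incomplete session pair).",
                    dropped))
  }
  d <- dplyr::filter(d, .data$participant %in% keep)
  if (dplyr::n_distinct(d$participant) < 4 ||
      dplyr::n_distinct(d$group) < 2) {
    abort("Need at least 2 complete participants per group.",
          class = "somtrack_insufficient_data")
  }

  an <- mixed_anova_interaction(d)
  rows <- tibble::tibble(
    test = "group x stimulation interaction",
    group = NA_character_,
    estimate = NA_real_, statistic = an$F,
    df1 = as.numeric(an$df1), df2 = as.numeric(an$df2),
    p.value = an$p, n = dplyr::n_distinct(d$participant)
  )
  for (g in sort(unique(d$group))) {
    wide <- tidyr::pivot_wider(d[d$group == g, ],
                               id_cols = "participant",
                               names_from = "condition",
                               values_from = "value")
    if (!all(c("cTBS", "no-cTBS") %in% names(wide))) next
    diff <- wide$cTBS - wide$`no-cTBS`
    tt <- t.test(diff, mu = 0)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      test = "paired t (cTBS - no-cTBS)", group = g,
      estimate = mean(diff), statistic = unname(tt$statistic),
      df1 = unname(tt$parameter), df2 = NA_real_,
      p.value = tt$p.value, n = length(diff)
    ))
  }
  rows
}
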