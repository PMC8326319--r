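#' Plot per-session SOM effect sizes
#'
#' Mean +/- SEM of the variance-weighted SOM effects, split by group and
#' stimulation condition when those columns are present (baseline data
#' collapses to one panel per pathway).
#'
#' @param object A [som_effects()] table.
#' @param measures Effect columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.som_effects <- function(object,
                                 measures = c("som_StoO_vw", "som_OtoS_vw"),
                                 ...) {
  d <- tidyr::pivot_longer(
    dplyr::filter(object, .data$converged),
    cols = dplyr::all_of(measures),
    names_to = "pathway", values_to = "effect"
  )
  grouping <- intersect(c("pathway", "group", "condition"), names(d))
  summ <- dplyr::summarise(
    dplyr::group_by(d, dplyr::across(dplyr::all_of(grouping))),
    mean = mean(.data$effect), sem = sd(.data$effect) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  x_var <- if ("condition" %in% grouping) "condition" else "pathway"
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data[[x_var]], y = .data$mean)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data[[x_var]]), width = 0.6,
                      show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(y = "SOM effect size (mean ± SEM)", x = NULL) +
    ggplot2::theme_minimal()
  if ("condition" %in% grouping && "group" %in% grouping) {
    p <- p + ggplot2::facet_grid(pathway ~ group)
  } else if ("pathway" %in% grouping && x_var != "pathway") {
    p <- p + ggplot2::facet_wrap(~pathway)
  }
  p
}

#' Interaction plot for the stimulation comparison
#'
#' Group-by-condition means (+/- SEM) of a raw-beta SOM effect, the visual
#' companion of [ctbs_interaction_test()].
#'
#' @param effects A [som_effects()] table with both sessions per
#'   participant.
#' @param measure Effect column (default `"som_StoO_raw"`).
#' @return A ggplot object.
#' @export
plot_ctbs_interaction <- function(effects, measure = "som_StoO_raw") {
  d <- dplyr::filter(effects, .data$converged, is.finite(.data[[measure]]))
  summ <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$condition),
    mean = mean(.data[[measure]]),
    sem = sd(.data[[measure]]) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$condition, y = .data$mean,
                                     group = .data$group,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = sprintf("%s (mean ± SEM)", measure),
                  colour = "group") +
    ggplot2::theme_minimal()
}
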