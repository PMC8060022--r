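#' Plot a psychometric fit
#'
#' Observed PREFER_PF proportions by stimulus (point size = trials at that
#' stimulus) with the fitted cumulative-normal curve, the PSE marked at the
#' 50% line.
#'
#' @param object A `psych_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psych_fit
#' @export
autoplot.psych_fit <- function(object, ...) {
  d <- object$data |>
    dplyr::mutate(r = response_to_binary(.data$response)) |>
    dplyr::group_by(.data$stimulus_deg) |>
    dplyr::summarise(p = mean(.data$r), n = dplyr::n(), .groups = "drop")
  xr <- range(d$stimulus_deg) + c(-1, 1) * 2
  curve <- tibble::tibble(
    x = seq(xr[1], xr[2], length.out = 200),
    p = psych_prob(seq(xr[1], xr[2], length.out = 200),
                   object$pse, object$slope, object$lapse)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stimulus_deg, y = .data$p)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$p),
                       color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::geom_vline(xintercept = object$pse, linetype = 2) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "ankle angle (deg, dorsiflexion +)",
                  y = "P(prefer plantarflexion)",
                  title = sprintf("PSE %.2f deg, Reliability Index %.2f deg",
                                  object$pse, object$reliability_index)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the running estimate trace of a session
#'
#' Stimuli and responses per trial with the running posterior PSE mean and
#' a +/- 1 posterior-SD band.
#'
#' @param session A `psych_session` (or its trial tibble).
#' @return A ggplot.
#' @export
plot_session_trace <- function(session) {
  trials <- if (inherits(session, "psych_session")) session$trials else session
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$trial_index)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$posterior_mean_deg - .data$posterior_sd_deg,
      ymax = .data$posterior_mean_deg + .data$posterior_sd_deg),
      fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$posterior_mean_deg),
                       color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$stimulus_deg,
                                     shape = .data$response,
                                     color = .data$phase)) +
    ggplot2::labs(x = "trial", y = "ankle angle (deg)",
                  shape = "response", color = "phase") +
    ggplot2::theme_minimal()
}

#' Plot cohort preferred angles by task
#'
#' Per-subject fitted preferences with group mean and SD, in the style of a
#' group-preference summary figure.
#'
#' @param study Tibble from [run_preference_study()] (columns `subject`,
#'   `task`, `pse`).
#' @return A ggplot.
#' @export
plot_cohort_preferences <- function(study) {
  stats_tbl <- study |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(mean_pse = mean(.data$pse), sd_pse = stats::sd(.data$pse),
                     .groups = "drop")
  ggplot2::ggplot(study, ggplot2::aes(x = .data$task, y = .data$pse)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::geom_pointrange(
      data = stats_tbl,
      ggplot2::aes(y = .data$mean_pse,
                   ymin = .data$mean_pse - .data$sd_pse,
                   ymax = .data$mean_pse + .data$sd_pse),
      color = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "task", y = "preferred ankle angle (deg)") +
    ggplot2::theme_minimal()
}

#' Plot mean condition curves over the gait cycle
#'
#' Mean curves per ankle angle, faceted by channel, for one or more tasks —
#' the standard way to show how socket pressures or shank pitch respond to
#' alignment.
#'
#' @param cond A `condition_summary` from [summarize_conditions()].
#' @param channels Channels to show (default all).
#' @return A ggplot.
#' @export
plot_condition_curves <- function(cond, channels = NULL) {
  curves <- cond$curves
  if (!is.null(channels)) {
    curves <- dplyr::filter(curves, .data$channel %in% channels)
  }
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$gait_pct,
                                       y = .data$mean_value,
                                       color = .data$ankle_angle,
                                       group = .data$ankle_angle)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(channel ~ task, scales = "free_y") +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = "% gait cycle", y = "mean value",
                  color = "ankle angle (deg)") +
    ggplot2::theme_minimal()
}
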