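#' Plot a task schedule
#'
#' Shows the better car and the actual winner per trial, with rating probes
#' marked along the bottom. Reversals in the volatile environment appear as
#' steps in the better-car line.
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#'
#' @return A ggplot object.
#' @export
plot_schedule <- function(schedule) {
  df <- dplyr::mutate(
    schedule,
    best_num = as.integer(.data$best_car == "A"),
    win_num = as.integer(.data$winner == "A")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_num),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$win_num),
                        shape = 3, colour = "steelblue") +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$is_rating_trial),
      ggplot2::aes(y = -0.15), shape = 17, colour = "darkorange"
    ) +
    ggplot2::scale_y_continuous(
      breaks = c(0, 1), labels = c("B", "A"),
      limits = c(-0.2, 1.05)
    ) +
    ggplot2::labs(
      x = "Trial", y = "Car",
      title = sprintf("%s schedule", df$environment[1]),
      subtitle = "line: better car; crosses: winner; triangles: rating probes"
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed and predicted happiness for a fitted model
#'
#' @param object A `happiness_fit`.
#' @param ... Unused.
#'
#' @return A ggplot object showing observed ratings and model predictions
#'   over rating trials.
#' @exportS3Method ggplot2::autoplot
autoplot.happiness_fit <- function(object, ...) {
  if (is.null(object$observed)) {
    stop("fit is flagged '", object$flag, "'; nothing to plot",
         call. = FALSE)
  }
  df <- tibble::tibble(
    trial = object$rating_trials,
    observed = object$observed,
    predicted = object$predicted
  )
  df_long <- tidyr::pivot_longer(df, c("observed", "predicted"),
                                 names_to = "series")
  ggplot2::ggplot(df_long,
                  ggplot2::aes(x = .data$trial, y = .data$value,
                               colour = .data$series,
                               linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(df_long,
                                             .data$series == "observed")) +
    ggplot2::scale_colour_manual(
      values = c(observed = "grey30", predicted = "firebrick")
    ) +
    ggplot2::labs(
      x = "Trial", y = "Happiness",
      title = sprintf("%s model (r² = %.2f)", object$model, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a random-effects model-selection result
#'
#' @param object A `bms_result`.
#' @param ... Unused.
#'
#' @return A ggplot bar chart of expected frequency and exceedance
#'   probability per model.
#' @exportS3Method ggplot2::autoplot
autoplot.bms_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tidy(object)[, c("model", "expected_frequency",
                     "exceedance_probability")],
    -"model", names_to = "measure"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Model", y = NULL,
                  title = "Random-effects model selection") +
    ggplot2::theme_minimal()
}

#' Plot parameter recovery
#'
#' Scatter of recovered against true per-subject parameter values, one
#' facet per environment, with the identity line.
#'
#' @param truth,fits Tibbles with `subject`, `environment` and the
#'   parameter column (same name in both).
#' @param parameter Name of the parameter column to plot.
#'
#' @return A ggplot object.
#' @export
plot_recovery <- function(truth, fits, parameter) {
  joined <- dplyr::inner_join(
    truth[, c("subject", "environment", parameter)],
    fits[, c("subject", "environment", parameter)],
    by = c("subject", "environment"), suffix = c("_true", "_rec")
  )
  ggplot2::ggplot(joined,
                  ggplot2::aes(x = .data[[paste0(parameter, "_true")]],
                               y = .data[[paste0(parameter, "_rec")]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~environment) +
    ggplot2::labs(x = sprintf("true %s", parameter),
                  y = sprintf("recovered %s", parameter)) +
    ggplot2::theme_minimal()
}
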