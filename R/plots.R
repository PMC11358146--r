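#' Plot a state repertoire as a centroid heat map
#'
#' ROIs on the x axis, states on the y axis; red = positive projection
#' (the ROIs detaching from the global mode), blue = negative.
#'
#' @param object A `state_repertoire`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot state_repertoire
#' @export
autoplot.state_repertoire <- function(object, ...) {
  df <- tidy(object)
  df$roi <- factor(df$roi, levels = unique(df$roi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi, y = factor(.data$state),
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick3", midpoint = 0) +
    ggplot2::labs(x = "ROI", y = "state", fill = "V1 weight",
                  title = sprintf("State repertoire (k = %d)", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot continuous rating traces coloured by condition
#'
#' @param ratings A tibble `subject_id, time_s, rating`.
#' @param labels A `condition_labels` table for the same grid.
#' @param max_subjects Thin to at most this many subjects (default 8).
#' @return A ggplot object.
#' @export
plot_ratings <- function(ratings, labels, max_subjects = 8) {
  ids <- head(unique(ratings$subject_id), max_subjects)
  df <- ratings |>
    dplyr::filter(.data$subject_id %in% ids) |>
    dplyr::inner_join(
      dplyr::select(as_tibble(labels), "t_mid_s", "label"),
      by = c(time_s = "t_mid_s"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$rating)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 0.4) +
    ggplot2::scale_colour_manual(values = c(happy = "#e08214", sad = "#5e3c99",
                                            neutral = "grey55",
                                            silence = "grey85")) +
    ggplot2::labs(x = "time (s)", y = "valence rating (-6..+6)",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' Plot the indirect-effect bootstrap distribution
#'
#' Histogram of the bootstrapped indirect effect `ab` with the
#' percentile confidence bounds and the point estimate.
#'
#' @param object A `mediation_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediation_fit
#' @export
autoplot.mediation_fit <- function(object, ...) {
  df <- tibble(ab = object$ab_boot)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ab)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$ci_ab, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$ab, colour = "firebrick3") +
    ggplot2::labs(
      x = "bootstrapped indirect effect ab",
      y = "resamples",
      title = sprintf("ab = %.3f, %d%% CI [%.3f, %.3f]", object$ab,
                      round(100 * object$ci_level),
                      object$ci_ab[1], object$ci_ab[2])) +
    ggplot2::theme_minimal()
}

#' Plot Dunn scores across candidate state counts
#'
#' @param repertoire A `state_repertoire`.
#' @return A ggplot object.
#' @export
plot_dunn <- function(repertoire) {
  df <- repertoire$dunn_by_k
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$dunn)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[which.max(df$dunn), ],
                        colour = "firebrick3", size = 3) +
    ggplot2::labs(x = "candidate k", y = "Dunn index") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
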