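#' Emotion-dynamics summaries of a rating trace
#'
#' Two within-subject variability statistics summarise a continuous
#' valence trace \eqn{x_1, \dots, x_n}:
#' \deqn{STD = \sqrt{\sum_i (x_i - \mu)^2 / n}}
#' \deqn{RMSSD = \sqrt{\sum_{i=1}^{n-1} (x_{i+1} - x_i)^2 / (n - 1)}}
#' with \eqn{\mu} the mean over the whole task. STD captures the overall
#' spread of emotional states (low = blunted responding); RMSSD captures
#' moment-to-moment lability. Note the population denominator `n` in STD
#' (no Bessel correction) — both are exactly the displayed affect-dynamics
#' forms of Jahng, Trull & Wood (2008).
#'
#' @param values Numeric rating sequence.
#' @return A single nonnegative number.
#' @examples
#' emotion_std(c(1, -1))    # 1
#' emotion_rmssd(c(0, 3, 0, 3))  # 3
#' @export
emotion_std <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) abort("`values` must be non-empty and gap-free")
  sqrt(sum((values - mean(values))^2) / length(values))
}

#' @rdname emotion_std
#' @export
emotion_rmssd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values)) {
    abort("`values` must have at least 2 samples and no gaps")
  }
  d <- diff(values)
  sqrt(sum(d^2) / length(d))
}

#' Mean rating per song condition
#'
#' Averages the per-volume ratings over volumes labelled `happy`, `sad`
#' and `neutral`; silence volumes are excluded. Conditions with no
#' volumes are dropped with a warning.
#'
#' @param rated_labels A `condition_labels` table carrying a `rating`
#'   column (see [resample_ratings()]).
#' @return A tibble with columns `condition` and `mean_rating`.
#' @export
condition_means <- function(rated_labels) {
  stopifnot(is.data.frame(rated_labels), "rating" %in% names(rated_labels))
  present <- rated_labels |>
    dplyr::filter(.data$label != "silence") |>
    dplyr::group_by(condition = .data$label) |>
    dplyr::summarise(mean_rating = mean(.data$rating), .groups = "drop")
  absent <- setdiff(c("happy", "sad", "neutral"), present$condition)
  if (length(absent)) {
    warn(paste0("no volumes for condition(s): ", paste(absent, collapse = ", ")))
  }
  dplyr::arrange(present, match(.data$condition, c("happy", "sad", "neutral")))
}

#' Cohort-level emotion-dynamics table
#'
#' Computes STD, RMSSD and per-condition mean ratings for every subject.
#' Statistics are computed over the entire analysed task including
#' silence volumes; set `exclude_silence = TRUE` to restrict STD/RMSSD to
#' music volumes only.
#'
#' @param ratings A data frame with columns `subject_id`, `time_s`,
#'   `rating` (stacked per-TR traces).
#' @param labels A `condition_labels` table for the common volume grid.
#' @param exclude_silence Drop silence volumes before computing STD and
#'   RMSSD (default `FALSE`).
#' @return A tibble `subject_id, std, rmssd, mean_happy, mean_sad,
#'   mean_neutral`.
#' @export
emotion_metrics <- function(ratings, labels, exclude_silence = FALSE) {
  ratings <- as_tibble(ratings)
  stopifnot(all(c("subject_id", "time_s", "rating") %in% names(ratings)))
  ratings |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(tr, key) {
      rl <- resample_ratings(tr, labels)
      x <- if (exclude_silence) rl$rating[rl$label != "silence"] else rl$rating
      cm <- suppressWarnings(condition_means(rl))
      wide <- setNames(as.list(cm$mean_rating), paste0("mean_", cm$condition))
      dplyr::bind_cols(
        tibble(std = emotion_std(x), rmssd = emotion_rmssd(x)),
        as_tibble(wide)
      )
    }) |>
    dplyr::ungroup()
}
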