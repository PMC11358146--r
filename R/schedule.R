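#' Parse and validate a stimulus schedule
#'
#' A stimulus schedule is an ordered table of timed musical pieces, each
#' carrying a valence label (`happy`, `sad` or `neutral`). Consecutive
#' pieces are separated by a constant silent gap, which is inferred from
#' the event times and stored in the `silence_s` attribute.
#'
#' @param rows A data frame with columns `index`, `start_s`, `end_s`,
#'   `label`, and optionally `title` and `composer`.
#' @return A tibble of class `stimulus_schedule`, sorted by onset, with
#'   attribute `silence_s` (the unique inter-piece gap in seconds; `NA`
#'   with a warning when fewer than two events are present).
#' @examples
#' sched <- parse_schedule(read_schedule(leidamood_example("stimulus_schedule.tsv")))
#' attr(sched, "silence_s")
#' @export
parse_schedule <- function(rows) {
  rows <- as_tibble(rows)
  required <- c("index", "start_s", "end_s", "label")
  missing <- setdiff(required, names(rows))
  if (length(missing)) {
    abort(paste0("schedule is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!nrow(rows)) abort("schedule has no events")
  if (!"title" %in% names(rows)) rows$title <- NA_character_
  if (!"composer" %in% names(rows)) rows$composer <- NA_character_

  bad_label <- !rows$label %in% c("happy", "sad", "neutral")
  if (any(bad_label)) {
    abort(sprintf("unknown label '%s' in schedule row %d",
                  rows$label[which(bad_label)[1]], which(bad_label)[1]))
  }
  bad_span <- rows$end_s <= rows$start_s
  if (any(bad_span)) {
    abort(sprintf("event in schedule row %d ends before it starts", which(bad_span)[1]))
  }
  rows <- dplyr::arrange(rows, .data$start_s)
  if (nrow(rows) > 1) {
    gaps <- rows$start_s[-1] - rows$end_s[-nrow(rows)]
    if (any(gaps < 0)) {
      abort(sprintf("schedule events overlap at row %d", which(gaps < 0)[1] + 1L))
    }
    if (length(unique(gaps)) > 1) {
      abort(sprintf("inter-piece gap is not constant (row %d breaks the pattern)",
                    which(gaps != gaps[1])[1] + 1L))
    }
    silence_s <- gaps[1]
  } else {
    warn("single-event schedule: inter-piece silence undefined")
    silence_s <- NA_real_
  }
  out <- rows[, c("index", "start_s", "end_s", "label", "title", "composer")]
  attr(out, "silence_s") <- silence_s
  class(out) <- c("stimulus_schedule", class(out))
  out
}

#' Read / write a stimulus schedule file
#'
#' Tab-separated text with header `index, start_s, end_s, label, title,
#' composer`. The packaged fixture `stimulus_schedule.tsv` holds the
#' 13-piece happy/sad/neutral programme used throughout the examples.
#'
#' @param path File path.
#' @return `read_schedule()`: a tibble of raw rows (pass to
#'   [parse_schedule()]); `write_schedule()`: `path`, invisibly.
#' @export
read_schedule <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_schedule
#' @param schedule A `stimulus_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_tsv(as_tibble(as.data.frame(schedule)), path)
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @export
leidamood_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "leidamood")))
  }
  system.file("extdata", file, package = "leidamood", mustWork = TRUE)
}

#' Map scanner volumes to song conditions
#'
#' Each volume `v` (0-based) covers clock time
#' `[dummy_offset_s + v*tr_s, dummy_offset_s + (v+1)*tr_s)` and receives
#' the label of the event containing its temporal midpoint, or `silence`
#' when the midpoint falls between pieces (or past the schedule's end).
#' Neutral pieces immediately preceded by a sad (resp. happy) piece
#' additionally carry the derived category `neutral_following_sad`
#' (resp. `neutral_following_happy`) for all of their volumes.
#'
#' Time 0 is the start of the analysed series, i.e. after any discarded
#' dummy scans; `dummy_offset_s` therefore defaults to 0 and is only
#' needed when the schedule clock starts before the analysed series.
#'
#' @param schedule A `stimulus_schedule`.
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Number of analysed volumes.
#' @param dummy_offset_s Seconds of the schedule clock discarded at run
#'   start (default 0).
#' @return A tibble of class `condition_labels` with one row per volume:
#'   `volume` (1-based), `t_mid_s`, `event` (event index or `NA` in
#'   silence), `label` in `{happy, sad, neutral, silence}`, `derived` in
#'   `{neutral_following_sad, neutral_following_happy, none}`. Attributes
#'   `tr_s` and `dummy_offset_s` record the grid.
#' @examples
#' sched <- parse_schedule(read_schedule(leidamood_example("stimulus_schedule.tsv")))
#' labs <- label_timepoints(sched, tr_s = 2, n_volumes = 254)
#' dplyr::count(labs, label)
#' @export
label_timepoints <- function(schedule, tr_s, n_volumes, dummy_offset_s = 0) {
  assert_scalar_number(tr_s, "tr_s", lower = 1e-12)
  assert_scalar_number(n_volumes, "n_volumes", lower = 1)
  stopifnot(inherits(schedule, "stimulus_schedule"))

  v <- seq_len(n_volumes) - 1L
  t_mid <- dummy_offset_s + (v + 0.5) * tr_s

  # half-open event windows [start, end)
  ev <- findInterval(t_mid, schedule$start_s)
  inside <- ev >= 1 & t_mid < schedule$end_s[pmax(ev, 1L)]
  event <- ifelse(inside, ev, NA_integer_)
  label <- ifelse(inside, schedule$label[pmax(ev, 1L)], "silence")

  prev_label <- c(NA_character_, schedule$label[-nrow(schedule)])
  derived_by_event <- dplyr::case_when(
    schedule$label == "neutral" & prev_label == "sad" ~ "neutral_following_sad",
    schedule$label == "neutral" & prev_label == "happy" ~ "neutral_following_happy",
    TRUE ~ "none"
  )
  derived <- ifelse(inside, derived_by_event[pmax(ev, 1L)], "none")

  out <- tibble(
    volume = v + 1L,
    t_mid_s = t_mid,
    event = as.integer(event),
    label = label,
    derived = derived
  )
  attr(out, "tr_s") <- tr_s
  attr(out, "dummy_offset_s") <- dummy_offset_s
  class(out) <- c("condition_labels", class(out))
  out
}

#' Resample a continuous rating trace onto the volume grid
#'
#' Ratings are assumed sampled on a uniform grid (`time_s` strictly
#' increasing with constant step). Each volume receives the trace value at
#' the sample nearest to the volume's temporal midpoint, ties broken
#' toward the earlier sample.
#'
#' @param trace A data frame with columns `time_s` and `rating`
#'   (ratings on the -6 ... +6 valence scale).
#' @param labels A `condition_labels` table from [label_timepoints()].
#' @return `labels` with an added `rating` column (one value per volume).
#' @export
resample_ratings <- function(trace, labels) {
  stopifnot(inherits(labels, "condition_labels"))
  trace <- as_tibble(trace)
  if (!all(c("time_s", "rating") %in% names(trace))) {
    abort("rating trace needs columns `time_s` and `rating`")
  }
  if (nrow(trace) < 2) abort("rating trace needs at least 2 samples")
  dt <- diff(trace$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt)) {
    abort("rating trace must be on a uniform, strictly increasing time grid")
  }
  if (any(abs(trace$rating) > 6 + 1e-9)) {
    abort("ratings outside the [-6, 6] scale")
  }
  dt <- dt[1]
  t0 <- trace$time_s[1]
  pos <- (labels$t_mid_s - t0) / dt
  idx <- ceiling(pos - 0.5) + 1L  # nearest sample, ties toward the earlier one
  if (any(idx < 1L) || any(idx > nrow(trace))) {
    abort(sprintf(
      "rating trace (%.1f..%.1f s) does not cover the labelled span (midpoints %.1f..%.1f s)",
      min(trace$time_s), max(trace$time_s), min(labels$t_mid_s), max(labels$t_mid_s)))
  }
  out <- labels
  out$rating <- trace$rating[idx]
  out
}
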