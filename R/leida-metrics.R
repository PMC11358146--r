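#' State occupancy, lifetime and switching metrics
#'
#' For a per-volume state sequence over states `1..k`:
#' * `occurrence(s)`: fraction of volumes assigned to `s`;
#' * `lifetime_trs(s)`: mean length (in TRs) of maximal consecutive runs
#'   of `s` (`NA` for states that never occur);
#' * `switching(i, j)`: transitions `i -> j` between consecutive volumes
#'   divided by all transitions out of `i`; self-transitions count in
#'   both the diagonal and the denominator, so every occurring row sums
#'   to 1. Rows of absent states are `NA`.
#'
#' @param states Integer state sequence (values in `1..k`).
#' @param k Number of states.
#' @return A list of class `state_metrics`: `occurrence` (length k,
#'   sums to 1), `lifetime_trs` (length k), `switching` (k x k), `k`,
#'   `n_volumes`.
#' @examples
#' m <- state_metrics(c(1, 1, 2, 2, 2, 1), k = 2)
#' m$occurrence     # 0.5 0.5
#' m$lifetime_trs   # 1.5 3
#' @export
state_metrics <- function(states, k) {
  states <- as.integer(states)
  if (!length(states)) abort("empty state sequence")
  if (any(states < 1 | states > k)) abort("state labels outside 1..k")
  tt <- length(states)

  occurrence <- tabulate(states, nbins = k) / tt

  runs <- run_lengths(states)
  lifetime <- vapply(seq_len(k), function(s) {
    ls <- runs$length[runs$value == s]
    if (length(ls)) mean(ls) else NA_real_
  }, 1)

  switching <- matrix(NA_real_, k, k)
  if (tt > 1) {
    from <- states[-tt]; to <- states[-1]
    counts <- table(factor(from, levels = seq_len(k)),
                    factor(to, levels = seq_len(k)))
    counts <- matrix(as.numeric(counts), k, k)
    out_of <- rowSums(counts)
    for (s in seq_len(k)) if (out_of[s] > 0) switching[s, ] <- counts[s, ] / out_of[s]
  }

  structure(list(occurrence = occurrence, lifetime_trs = lifetime,
                 switching = switching, k = k, n_volumes = tt),
            class = "state_metrics")
}

#' @rdname state_metrics
#' @param x A `state_metrics` object.
#' @param tr_s Optional TR in seconds; adds a `lifetime_s` column.
#' @param ... Unused.
#' @return `tidy()`: a tibble `state, occurrence, lifetime_trs`
#'   (plus `lifetime_s` when `tr_s` is given).
#' @method tidy state_metrics
#' @export
tidy.state_metrics <- function(x, tr_s = NULL, ...) {
  out <- tibble(state = seq_len(x$k), occurrence = x$occurrence,
                lifetime_trs = x$lifetime_trs)
  if (!is.null(tr_s)) out$lifetime_s <- out$lifetime_trs * tr_s
  out
}

#' Condition-restricted state metrics
#'
#' Restricts the state metrics to the volumes of one song condition
#' (`happy`, `sad`, `neutral`) or derived category
#' (`neutral_following_sad`, `neutral_following_happy`). Metrics are
#' computed per song first — runs and transitions are truncated at song
#' boundaries — then averaged (unweighted) across all songs of the type,
#' matching the per-song-type analysis convention.
#'
#' @param states Integer state sequence on the labelled volume grid.
#' @param labels A `condition_labels` table of the same length.
#' @param condition One of the three labels or two derived categories.
#' @param k Number of states.
#' @return A `state_metrics` object whose fields are song-averages
#'   (lifetime averaged over songs where the state occurs).
#' @export
condition_metrics <- function(states, labels, condition, k) {
  stopifnot(inherits(labels, "condition_labels"))
  states <- as.integer(states)
  if (length(states) != nrow(labels)) abort("states and labels differ in length")
  col <- if (condition %in% c("neutral_following_sad", "neutral_following_happy")) {
    labels$derived
  } else {
    labels$label
  }
  keep <- col == condition & !is.na(labels$event)
  if (!any(keep)) abort(sprintf("no volumes carry condition '%s'", condition))

  per_song <- lapply(split(which(keep), labels$event[keep]), function(idx) {
    state_metrics(states[idx], k)
  })
  occ <- rowMeans(vapply(per_song, `[[`, numeric(k), "occurrence"))
  lt_mat <- vapply(per_song, `[[`, numeric(k), "lifetime_trs")
  lt_mat <- matrix(lt_mat, nrow = k)
  lifetime <- rowMeans(lt_mat, na.rm = TRUE)
  lifetime[is.nan(lifetime)] <- NA_real_
  sw <- Reduce(`+`, lapply(per_song, function(m) {
    s <- m$switching; s[is.na(s)] <- 0; s
  })) / length(per_song)

  structure(list(occurrence = occ, lifetime_trs = lifetime, switching = sw,
                 k = k, n_volumes = sum(keep), n_songs = length(per_song),
                 condition = condition),
            class = "state_metrics")
}

#' Tidy cohort table of LEiDA metrics
#'
#' One row per subject x state, with occupancy and lifetime (TRs and
#' seconds); optionally restricted to a condition.
#'
#' @param repertoire A `state_repertoire` from [pool_and_cluster()].
#' @param tr_s TR in seconds (for the `lifetime_s` column).
#' @param labels Optional `condition_labels`; with `condition`, restricts
#'   metrics per [condition_metrics()].
#' @param condition Optional condition name.
#' @return A tibble `subject_id, state, occurrence, lifetime_trs,
#'   lifetime_s`.
#' @export
metrics_table <- function(repertoire, tr_s, labels = NULL, condition = NULL) {
  stopifnot(inherits(repertoire, "state_repertoire"))
  purrr::imap_dfr(repertoire$assignments, function(seq, id) {
    m <- if (is.null(condition)) {
      state_metrics(seq, repertoire$k)
    } else {
      condition_metrics(seq, labels, condition, repertoire$k)
    }
    dplyr::mutate(tidy(m, tr_s = tr_s), subject_id = id, .before = 1)
  })
}
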