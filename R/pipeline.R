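#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable the pipeline exposes. All randomness (k-means
#' restarts, mediation bootstrap) flows from the single `seed` through a
#' fixed per-stage derivation rule.
#'
#' @param input_dir Cohort directory in the [write_cohort()] layout
#'   (ignored when a cohort object is passed to [run_full()] directly).
#' @param tr_s Repetition time, seconds.
#' @param k_min,k_max Candidate state-count range.
#' @param n_restarts k-means restarts per candidate k.
#' @param seed Master seed (required).
#' @param n_boot Mediation bootstrap resamples.
#' @param ci_level Bootstrap confidence level.
#' @param fdr_q False-discovery-rate level for the correlation screens.
#' @param bandpass Optional `c(lo_hz, hi_hz)`: FFT band-pass applied to
#'   each ROI series before phase extraction (default `NULL`, off).
#' @param binarize_centroids Correlate binarized positive projections
#'   instead of signed centroids when labelling states (default `FALSE`).
#' @param covariates_in_mediation Residualise the mediation variables on
#'   age, gender and music background first (default `FALSE`).
#' @param exclude_silence Exclude silence volumes from STD/RMSSD.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, tr_s = 2, k_min = 5, k_max = 10,
                       n_restarts = 50, seed, n_boot = 5000, ci_level = 0.95,
                       fdr_q = 0.05, bandpass = NULL,
                       binarize_centroids = FALSE,
                       covariates_in_mediation = FALSE,
                       exclude_silence = FALSE) {
  if (missing(seed)) abort("`seed` is required")
  stopifnot(k_min <= k_max, fdr_q > 0, fdr_q < 1)
  structure(as.list(environment()), class = "run_config")
}

# brick-wall FFT band-pass, applied per demeaned column
fft_bandpass <- function(x, lo_hz, hi_hz, tr_s) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) / (n * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)  # two-sided
  keep <- freqs >= lo_hz & freqs <= hi_hz
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE) / n)
}

#' Run the full analysis pipeline
#'
#' Phases, leading eigenvectors, pooled clustering with Dunn-index k
#' selection, network labelling, emotion metrics, covariate-controlled
#' correlation screens with FDR control, the bootstrap mediation model,
#' condition-restricted metrics and the median-split summary.
#'
#' The mediation uses the occupancy of the focal state (the state whose
#' occupancy correlates most strongly with the anhedonia score) as IV,
#' the anhedonia score as mediator, and the rating STD as DV.
#'
#' @param cohort A `synthetic_cohort` (or the same shape read from disk);
#'   if `NULL`, read from `config$input_dir`.
#' @param config A `run_config`.
#' @param out_dir Optional output directory; when given, all result
#'   tables are written as TSV plus a JSON run manifest.
#' @return A list of class `leida_run`: `repertoire`, `state_labels`,
#'   `emotion`, `cohort_table`, `correlations`, `mediation`,
#'   `condition_occupancy`, `median_split_summary`, `labels`, `manifest`.
#' @export
run_full <- function(cohort = NULL, config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    if (is.null(config$input_dir)) abort("no cohort and no `input_dir`")
    cohort <- read_cohort(config$input_dir)
  }
  check_cohort_ids(cohort)

  n_volumes <- nrow(cohort$timeseries[[1]])
  labels <- label_timepoints(cohort$schedule, config$tr_s, n_volumes)

  eigs <- lapply(cohort$timeseries, function(x) {
    if (nrow(x) != n_volumes) {
      abort("subjects differ in volume count")
    }
    if (!is.null(config$bandpass)) {
      x <- apply(x, 2, function(col) {
        fft_bandpass(col - mean(col), config$bandpass[1], config$bandpass[2],
                     config$tr_s)
      })
    }
    leading_eigenvectors(compute_phases(x))$v1
  })
  repertoire <- pool_and_cluster(eigs, k_min = config$k_min,
                                 k_max = config$k_max, seed = config$seed,
                                 n_restarts = config$n_restarts)
  state_labels <- label_states_maybe_binarized(repertoire, cohort$membership,
                                               config$binarize_centroids)

  emotion <- emotion_metrics(cohort$ratings, labels,
                             exclude_silence = config$exclude_silence)

  occ_wide <- metrics_table(repertoire, config$tr_s) |>
    dplyr::select("subject_id", "state", "occurrence", "lifetime_trs") |>
    tidyr::pivot_wider(names_from = "state",
                       values_from = c("occurrence", "lifetime_trs"),
                       names_sep = "_state")
  cohort_table <- cohort$meta |>
    dplyr::inner_join(emotion, by = "subject_id") |>
    dplyr::inner_join(occ_wide, by = "subject_id") |>
    dplyr::mutate(gender_num = as.integer(factor(.data$gender)) - 1L)

  covars <- c("age", "gender_num", "music_background")
  k <- repertoire$k
  screen <- function(xvar, yvars) {
    rows <- purrr::map_dfr(yvars, function(yv) {
      # a metric can be degenerate in small cohorts (e.g. a state with a
      # constant lifetime); report it as NA rather than aborting the run
      tryCatch(partial_pearson(cohort_table, xvar, yv, covariates = covars),
               error = function(e) {
                 tibble(x = xvar, y = yv,
                        covariates = paste(covars, collapse = ","),
                        n = NA_integer_, r = NA_real_, p = NA_real_)
               })
    })
    adj <- fdr_bh(rows$p, config$fdr_q)
    dplyr::mutate(rows, p_fdr = adj$p_fdr, reject = adj$reject)
  }
  occ_cols <- paste0("occurrence_state", seq_len(k))
  lt_cols <- paste0("lifetime_trs_state", seq_len(k))
  correlations <- dplyr::bind_rows(
    emotion_vs_masq = screen("masq_ad", c("std", "rmssd")),
    occurrence_vs_masq = screen("masq_ad", occ_cols),
    lifetime_vs_masq = screen("masq_ad", lt_cols),
    occurrence_vs_std = screen("std", occ_cols),
    .id = "family"
  )

  occ_masq <- correlations[correlations$family == "occurrence_vs_masq", ]
  focal_state <- which.max(abs(occ_masq$r))
  med_data <- tibble(
    iv = cohort_table[[occ_cols[focal_state]]],
    m = as.numeric(cohort_table$masq_ad),
    dv = cohort_table$std
  )
  if (config$covariates_in_mediation) {
    zmat <- stats::model.matrix(~ age + gender_num + music_background,
                                data = cohort_table)
    med_data <- dplyr::mutate(med_data, dplyr::across(
      dplyr::everything(),
      ~ stats::lsfit(zmat, .x, intercept = FALSE)$residuals))
  }
  mediation <- mediate(med_data, "iv", "m", "dv", n_boot = config$n_boot,
                       ci_level = config$ci_level, seed = config$seed)

  conds <- c("happy", "sad", "neutral",
             "neutral_following_sad", "neutral_following_happy")
  condition_occupancy <- purrr::map_dfr(conds, function(cd) {
    metrics_table(repertoire, config$tr_s, labels = labels, condition = cd) |>
      dplyr::mutate(condition = cd, .before = 2)
  })

  groups <- tibble(subject_id = cohort_table$subject_id,
                   group = median_split(cohort_table$masq_ad))
  median_split_summary <- condition_occupancy |>
    dplyr::filter(.data$state == focal_state,
                  .data$condition %in% c("sad", "neutral_following_sad")) |>
    dplyr::inner_join(groups, by = "subject_id") |>
    dplyr::group_by(.data$condition, .data$group) |>
    dplyr::summarise(mean_occurrence = mean(.data$occurrence),
                     sd_occurrence = sd(.data$occurrence), .groups = "drop")

  manifest <- list(
    package_version = as.character(utils::packageVersion("leidamood")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config[setdiff(names(config), "input_dir")],
    n_subjects = length(cohort$timeseries),
    n_volumes = n_volumes,
    n_rois = ncol(cohort$timeseries[[1]]),
    selected_k = repertoire$k,
    focal_state = focal_state,
    dunn_by_k = as.data.frame(repertoire$dunn_by_k)
  )

  out <- structure(list(
    repertoire = repertoire, state_labels = state_labels, emotion = emotion,
    cohort_table = cohort_table, correlations = correlations,
    mediation = mediation, condition_occupancy = condition_occupancy,
    median_split_summary = median_split_summary, labels = labels,
    focal_state = focal_state, manifest = manifest
  ), class = "leida_run")

  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

label_states_maybe_binarized <- function(repertoire, membership, binarize) {
  cents <- repertoire$centroids
  if (binarize) {
    cents <- (cents > 0) * 1
    keep_ok <- apply(cents, 1, stats::sd) > 0
    cents[!keep_ok, 1] <- 1e-9  # avoid zero-variance rows for all-negative states
  }
  rep2 <- repertoire
  rep2$centroids <- cents
  label_states(rep2, membership)
}

check_cohort_ids <- function(cohort) {
  ids <- names(cohort$timeseries)
  rat_ids <- unique(cohort$ratings$subject_id)
  meta_ids <- cohort$meta$subject_id
  for (set in list(c("ratings", setdiff(ids, rat_ids)),
                   c("metadata", setdiff(ids, meta_ids)))) {
    if (length(set) > 1 && nzchar(set[2])) {
      abort(sprintf("subject '%s' missing from %s", set[2], set[1]))
    }
  }
  invisible(TRUE)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(as_tibble(as.data.frame(run$repertoire$centroids)),
                   file.path(out_dir, "state_centroids.tsv"))
  readr::write_tsv(run$state_labels, file.path(out_dir, "state_labels.tsv"))
  readr::write_tsv(run$emotion, file.path(out_dir, "emotion_metrics.tsv"))
  readr::write_tsv(run$correlations, file.path(out_dir, "correlations.tsv"))
  readr::write_tsv(tidy(run$mediation), file.path(out_dir, "mediation.tsv"))
  readr::write_tsv(run$condition_occupancy,
                   file.path(out_dir, "condition_occupancy.tsv"))
  readr::write_tsv(run$median_split_summary,
                   file.path(out_dir, "median_split_summary.tsv"))
  seqs <- purrr::imap_dfr(run$repertoire$assignments, function(s, id) {
    tibble(subject_id = id, volume = seq_along(s), state = s)
  })
  readr::write_tsv(seqs, file.path(out_dir, "state_sequences.tsv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.leida_run <- function(x, ...) {
  cat(sprintf("LEiDA run: k = %d states, %d subjects, focal state %d\n",
              x$repertoire$k, length(x$repertoire$assignments), x$focal_state))
  print(x$mediation)
  invisible(x)
}

#' Generate a synthetic cohort on disk
#'
#' Convenience wrapper: simulate with [simulate_cohort()] and write with
#' [write_cohort()]. Warns when the planted state count falls outside
#' the model-selection search range.
#'
#' @param cfg A `generator_config`.
#' @param dir Output directory.
#' @param k_min,k_max Search range the cohort is destined for.
#' @return The cohort, invisibly.
#' @export
run_generate <- function(cfg, dir, k_min = 5, k_max = 10) {
  if (cfg$planted_k < k_min || cfg$planted_k > k_max) {
    warn(sprintf("planted_k = %d lies outside the search range [%d, %d]; model selection cannot recover it",
                 cfg$planted_k, k_min, k_max))
  }
  cohort <- simulate_cohort(cfg)
  write_cohort(cohort, dir)
  invisible(cohort)
}
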