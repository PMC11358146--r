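#' Configuration for the synthetic-cohort generator
#'
#' Defaults mirror the study design the package analyses: 31 subjects,
#' 105 ROIs, 250 analysed volumes at TR 2 s, a 13-piece happy/sad/neutral
#' music programme, MASQ-AD-like anhedonia scores on the 14-70 scale
#' (population mean 34.26, SD 8.84), and a planted standardized mediation
#' chain `occupancy -(a)-> anhedonia -(b)-> rating amplitude` with
#' a = 0.54, b = -0.62.
#'
#' The BOLD model: a Markov chain over `planted_k` states (geometric
#' dwell, mean `dwell_mean_trs`) drives a common carrier oscillation
#' (`carrier_hz`, upper BOLD band, with slow phase jitter); ROIs in the
#' active state's community run in anti-phase (pi shift) to the rest, so
#' the community is exactly the positive-projection set of the leading
#' eigenvector in the noiseless limit. Per-ROI phase noise
#' (`phase_noise_sd`, radians) is added and the BOLD value is the cosine
#' of the phase. One designated attention-like state (state 1) has its
#' entry probability tilted by a subject-level loading (`dan_tilt`),
#' creating the occupancy differences that feed the mediation chain.
#'
#' @param n_subjects,n_rois,n_volumes,tr_s Cohort dimensions.
#' @param planted_k Number of planted states (>= 2).
#' @param dwell_mean_trs Mean state dwell time in TRs.
#' @param phase_noise_sd Per-ROI phase noise, radians.
#' @param carrier_hz Carrier frequency of the common oscillation, Hz.
#' @param phase_jitter_sd Per-volume jitter of the carrier phase, radians.
#' @param dan_tilt Scale of the subject loading on state 1's entry odds.
#' @param a_true,b_true Planted standardized path coefficients.
#' @param masq_range,masq_mean,masq_sd Score scale for the anhedonia
#'   questionnaire totals.
#' @param base_amp Baseline rating amplitude (rating units) for happy
#'   (+) and sad (-) pieces; neutral targets 0.
#' @param amp_spread Relative between-subject spread of the amplitude.
#' @param rating_noise_sd Per-volume rating noise, rating units.
#' @param seed Integer master seed (required).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 31, n_rois = 105, n_volumes = 250,
                             tr_s = 2, planted_k = 6, dwell_mean_trs = 10,
                             phase_noise_sd = 0.3, carrier_hz = 0.1,
                             phase_jitter_sd = 0.05, dan_tilt = 0.6,
                             a_true = 0.54, b_true = -0.62,
                             masq_range = c(14L, 70L), masq_mean = 34.26,
                             masq_sd = 8.843, base_amp = 3, amp_spread = 0.4,
                             rating_noise_sd = 0.8, seed) {
  if (missing(seed)) abort("`seed` is required")
  stopifnot(planted_k >= 2, dwell_mean_trs >= 1, n_rois >= 2 * planted_k,
            masq_range[1] >= 14, masq_range[2] <= 70,
            abs(a_true) <= 1, abs(b_true) <= 1)
  cfg <- as.list(environment())
  cfg$roi_names <- sprintf("ROI%03d", seq_len(n_rois))
  # disjoint, equally sized communities; leftover ROIs stay in the
  # global (never anti-phase) pool, keeping planted centroids orthogonal
  comm_size <- floor(n_rois / (planted_k + 1))
  cfg$communities <- lapply(seq_len(planted_k), function(s) {
    seq.int((s - 1) * comm_size + 1, s * comm_size)
  })
  structure(cfg, class = "generator_config")
}

#' Generate planted-state BOLD timeseries
#'
#' @param cfg A `generator_config`.
#' @return A list with `timeseries` (named list of T x N matrices),
#'   `states` (named list of planted per-volume state sequences),
#'   `occupancy` (subjects x states tibble of planted fractional
#'   occupancies) and `dan_loading` (the subject-level tilt draws).
#' @export
gen_state_timeseries <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  k <- cfg$planted_k
  ids <- sprintf("sub%03d", seq_len(cfg$n_subjects))
  member <- matrix(FALSE, cfg$n_rois, k)
  for (s in seq_len(k)) member[cfg$communities[[s]], s] <- TRUE

  set.seed(derive_seed(cfg$seed, 1))
  dan_loading <- rnorm(cfg$n_subjects)

  p_stay <- 1 - 1 / cfg$dwell_mean_trs
  omega <- 2 * pi * cfg$carrier_hz * cfg$tr_s

  ts_list <- vector("list", cfg$n_subjects)
  st_list <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    set.seed(derive_seed(cfg$seed, 1000 + i))
    w <- rep(1, k)
    w[1] <- exp(cfg$dan_tilt * dan_loading[i])  # attention-like state tilt

    states <- integer(cfg$n_volumes)
    states[1] <- sample.int(k, 1, prob = w)
    for (t in 2:cfg$n_volumes) {
      if (runif(1) < p_stay) {
        states[t] <- states[t - 1]
      } else {
        ws <- w; ws[states[t - 1]] <- 0
        states[t] <- sample.int(k, 1, prob = ws)
      }
    }

    carrier <- cumsum(c(runif(1, -pi, pi),
                        rep(omega, cfg$n_volumes - 1) +
                          rnorm(cfg$n_volumes - 1, 0, cfg$phase_jitter_sd)))
    antiphase <- member[, states] * pi                    # N x T
    noise <- matrix(rnorm(cfg$n_rois * cfg$n_volumes, 0, cfg$phase_noise_sd),
                    cfg$n_rois, cfg$n_volumes)
    theta <- sweep(antiphase + noise, 2, carrier, `+`)
    x <- t(cos(theta))
    colnames(x) <- cfg$roi_names
    ts_list[[i]] <- x
    st_list[[i]] <- states
  }
  names(ts_list) <- names(st_list) <- ids

  occupancy <- purrr::imap_dfr(st_list, function(s, id) {
    tibble(subject_id = id, state = seq_len(k),
           occupancy = tabulate(s, nbins = k) / length(s))
  })
  list(timeseries = ts_list, states = st_list, occupancy = occupancy,
       dan_loading = dan_loading)
}

#' Generate behaviour: anhedonia scores and rating traces
#'
#' The planted chain: the standardized anhedonia latent is
#' `a_true * z(occupancy of state 1) + sqrt(1 - a_true^2) * noise`,
#' mapped onto the questionnaire's integer score scale. Each subject's
#' rating amplitude multiplier is
#' `1 + amp_spread * (b_true * z(score) + sqrt(1 - b_true^2) * eps)` —
#' the subject-level disturbance `eps` makes `b_true` the planted
#' standardized path rather than a deterministic link. Negative `b_true`
#' yields blunting: higher anhedonia, flatter ratings. Ratings follow
#' the 13-piece programme on the TR grid (`+amp` happy, `-amp` sad, 0
#' neutral and silence) plus Gaussian noise, clipped to [-6, 6].
#'
#' @param cfg A `generator_config`.
#' @param dan_occupancy Numeric vector: per-subject planted occupancy of
#'   the designated attention-like state (state 1), in `[0, 1]`.
#' @return A list with `meta` (tibble `subject_id, masq_ad, age, gender,
#'   music_background`), `ratings` (tibble `subject_id, time_s, rating`
#'   on the TR grid), `amp` (per-subject amplitudes) and `labels` (the
#'   `condition_labels` grid used).
#' @export
gen_behaviour <- function(cfg, dan_occupancy) {
  stopifnot(inherits(cfg, "generator_config"),
            all(dan_occupancy >= 0 & dan_occupancy <= 1),
            length(dan_occupancy) == cfg$n_subjects)
  ids <- sprintf("sub%03d", seq_len(cfg$n_subjects))
  set.seed(derive_seed(cfg$seed, 2))

  z_occ <- safe_z(dan_occupancy)
  latent <- cfg$a_true * z_occ +
    sqrt(1 - cfg$a_true^2) * rnorm(cfg$n_subjects)
  masq <- round(cfg$masq_mean + cfg$masq_sd * latent)
  masq <- pmin(pmax(masq, cfg$masq_range[1]), cfg$masq_range[2])

  z_masq <- safe_z(masq)
  eps <- rnorm(cfg$n_subjects)
  amp <- cfg$base_amp *
    (1 + cfg$amp_spread * (cfg$b_true * z_masq + sqrt(1 - cfg$b_true^2) * eps))
  if (any(amp <= 0)) {
    warn(sprintf("%d subject(s) hit the zero-amplitude floor", sum(amp <= 0)))
    amp <- pmax(amp, 0)
  }

  sched <- default_schedule()
  labels <- label_timepoints(sched, cfg$tr_s, cfg$n_volumes)
  g <- dplyr::case_when(labels$label == "happy" ~ 1,
                        labels$label == "sad" ~ -1,
                        TRUE ~ 0)

  ratings <- purrr::map_dfr(seq_len(cfg$n_subjects), function(i) {
    r <- amp[i] * g + rnorm(cfg$n_volumes, 0, cfg$rating_noise_sd)
    tibble(subject_id = ids[i], time_s = labels$t_mid_s,
           rating = pmin(pmax(r, -6), 6))
  })

  meta <- tibble(
    subject_id = ids,
    masq_ad = as.integer(masq),
    age = sample(18:30, cfg$n_subjects, replace = TRUE),
    gender = sample(c("F", "M"), cfg$n_subjects, replace = TRUE),
    music_background = sample(1:5, cfg$n_subjects, replace = TRUE)
  )
  list(meta = meta, ratings = ratings, amp = amp, labels = labels)
}

#' The packaged 13-piece stimulus programme
#'
#' @return A `stimulus_schedule` parsed from the shipped fixture.
#' @export
default_schedule <- function() {
  parse_schedule(read_schedule(leidamood_example("stimulus_schedule.tsv")))
}

#' Simulate a full synthetic cohort
#'
#' Runs [gen_state_timeseries()] and [gen_behaviour()] and bundles the
#' results together with the planted ground truth.
#'
#' @param cfg A `generator_config`.
#' @return An object of class `synthetic_cohort`: `timeseries`,
#'   `ratings`, `meta`, `schedule`, `membership` (synthetic 7-network
#'   table over the generator ROIs) and `truth` (planted states,
#'   occupancies, communities, `a_true`, `b_true`, `ab_true`,
#'   `dan_state`, amplitudes).
#' @export
simulate_cohort <- function(cfg) {
  brain <- gen_state_timeseries(cfg)
  occ1 <- brain$occupancy$occupancy[brain$occupancy$state == 1]
  beh <- gen_behaviour(cfg, occ1)
  structure(list(
    timeseries = brain$timeseries,
    ratings = beh$ratings,
    meta = beh$meta,
    schedule = default_schedule(),
    membership = synthetic_membership(cfg$roi_names),
    tr_s = cfg$tr_s,
    truth = list(
      states = brain$states,
      occupancy = brain$occupancy,
      communities = cfg$communities,
      dan_state = 1L,
      dan_loading = brain$dan_loading,
      amp = beh$amp,
      a_true = cfg$a_true, b_true = cfg$b_true,
      ab_true = cfg$a_true * cfg$b_true,
      planted_k = cfg$planted_k,
      dwell_mean_trs = cfg$dwell_mean_trs,
      seed = cfg$seed
    )
  ), class = "synthetic_cohort")
}

# Synthetic block assignment of ROIs to the seven canonical networks.
# Purely for self-contained examples/tests; not an empirical atlas map.
# Dorsal attention takes the first block so the generator's tilted
# state-1 community overlaps it.
synthetic_membership <- function(roi_names) {
  nets <- c("dorsal attention", "visual", "somato-motor", "ventral attention",
            "limbic", "fronto-parietal", "default-mode")
  n <- length(roi_names)
  block <- rep(nets, each = ceiling(n / 7))[seq_len(n)]
  tibble(roi_name = roi_names, network = block)
}

#' Write / read a synthetic cohort as plain-text files
#'
#' Emits exactly the formats the pipeline consumes: per-subject
#' `timeseries/<id>.tsv` (volumes x ROIs, header = ROI names),
#' `ratings/<id>.tsv` (`time_s, rating`), cohort-level `meta.tsv`,
#' `schedule.tsv`, `membership.tsv`, and `truth.json` (the planted
#' ground truth, for tests).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: a
#'   `synthetic_cohort`-shaped list read back from disk (with `truth`
#'   when `truth.json` is present).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ratings"), showWarnings = FALSE)
  for (id in names(cohort$timeseries)) {
    readr::write_tsv(as_tibble(as.data.frame(cohort$timeseries[[id]])),
                     file.path(dir, "timeseries", paste0(id, ".tsv")))
  }
  for (id in unique(cohort$ratings$subject_id)) {
    readr::write_tsv(
      cohort$ratings[cohort$ratings$subject_id == id, c("time_s", "rating")],
      file.path(dir, "ratings", paste0(id, ".tsv")))
  }
  readr::write_tsv(cohort$meta, file.path(dir, "meta.tsv"))
  write_schedule(cohort$schedule, file.path(dir, "schedule.tsv"))
  readr::write_tsv(cohort$membership, file.path(dir, "membership.tsv"))
  truth <- cohort$truth
  truth$occupancy <- as.data.frame(truth$occupancy)
  jsonlite::write_json(c(truth, list(tr_s = cohort$tr_s)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ts_files <- sort(dir(file.path(dir, "timeseries"), full.names = TRUE))
  ids <- sub("\\.tsv$", "", basename(ts_files))
  timeseries <- lapply(ts_files, function(f) {
    as.matrix(readr::read_tsv(f, show_col_types = FALSE))
  })
  names(timeseries) <- ids
  rt_files <- file.path(dir, "ratings", paste0(ids, ".tsv"))
  missing <- !file.exists(rt_files)
  if (any(missing)) {
    abort(sprintf("missing ratings for subject '%s'", ids[which(missing)[1]]))
  }
  ratings <- purrr::map2_dfr(rt_files, ids, function(f, id) {
    dplyr::mutate(readr::read_tsv(f, show_col_types = FALSE),
                  subject_id = id, .before = 1)
  })
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    tr$occupancy <- as_tibble(tr$occupancy)
    tr
  }
  structure(list(
    timeseries = timeseries,
    ratings = ratings,
    meta = readr::read_tsv(file.path(dir, "meta.tsv"), show_col_types = FALSE),
    schedule = parse_schedule(read_schedule(file.path(dir, "schedule.tsv"))),
    membership = read_network_membership(file.path(dir, "membership.tsv")),
    tr_s = truth$tr_s %||% 2,
    truth = truth
  ), class = "synthetic_cohort")
}
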