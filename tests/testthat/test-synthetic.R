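test_that("generation is fully deterministic under a fixed seed", {
  cfg <- generator_config(n_subjects = 3, n_rois = 35, n_volumes = 60, seed = 91)
  c1 <- suppressWarnings(simulate_cohort(cfg))
  c2 <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(c1$timeseries, c2$timeseries)
  expect_identical(c1$ratings, c2$ratings)
  expect_identical(c1$meta, c2$meta)
  expect_identical(c1$truth$states, c2$truth$states)
})

test_that("two writes with the same seed produce byte-identical files", {
  cfg <- generator_config(n_subjects = 2, n_rois = 21, n_volumes = 40, seed = 92)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(suppressWarnings(simulate_cohort(cfg)), d1)
  write_cohort(suppressWarnings(simulate_cohort(cfg)), d2)
  f1 <- sort(dir(d1, recursive = TRUE))
  expect_identical(f1, sort(dir(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("cohort invariants hold: ranges, dimensions, truth consistency", {
  co <- cached_cohort()
  expect_true(all(abs(co$ratings$rating) <= 6))
  expect_true(all(co$meta$masq_ad >= 14 & co$meta$masq_ad <= 70))
  expect_equal(length(co$truth$states), length(co$timeseries))
  for (id in names(co$timeseries)) {
    expect_equal(nrow(co$timeseries[[id]]), length(co$truth$states[[id]]))
  }
  occ <- co$truth$occupancy
  sums <- tapply(occ$occupancy, occ$subject_id, sum)
  expect_equal(as.numeric(sums), rep(1, 12), tolerance = 1e-12)
})

test_that("the anti-phase construction makes the community the positive set", {
  # planted phases directly: carrier + pi inside the active community
  cfg <- generator_config(n_subjects = 1, n_rois = 35, n_volumes = 40,
                          phase_noise_sd = 0, seed = 93)
  comm <- cfg$communities[[3]]
  for (carrier in c(0.2, 1.9, -2.5)) {
    theta <- rep(carrier, 35)
    theta[comm] <- carrier + pi
    e <- leading_eigenvector(phase_locking_matrix(theta),
                             check_degenerate = FALSE)
    expect_identical(which(e$vector > 0), comm)
    expect_true(all(e$vector[-comm] < 0))
  }
})

test_that("a noiseless cohort is recovered almost perfectly by the pipeline", {
  cfg <- generator_config(n_subjects = 4, n_rois = 70, n_volumes = 150,
                          phase_noise_sd = 0, phase_jitter_sd = 0, seed = 94)
  co <- suppressWarnings(simulate_cohort(cfg))
  eigs <- lapply(co$timeseries, function(x) leading_eigenvectors(compute_phases(x))$v1)
  rep <- pool_and_cluster(eigs, seed = 94, n_restarts = 10)
  expect_equal(rep$k, cfg$planted_k)
  acc <- assignment_accuracy(unlist(rep$assignments), unlist(co$truth$states),
                             cfg$planted_k)
  expect_gte(acc, 0.95)
})

test_that("planted dwell times follow the Markov-chain expectation", {
  cfg <- generator_config(n_subjects = 20, n_rois = 21, n_volumes = 200,
                          dwell_mean_trs = 5, seed = 95)
  brain <- gen_state_timeseries(cfg)
  lt <- unlist(lapply(brain$states, function(s) rle(s)$lengths))
  expect_equal(mean(lt), 5, tolerance = 1)
})

test_that("noiseless ratings match the closed-form schedule STD", {
  cfg <- generator_config(n_subjects = 6, n_volumes = 250, amp_spread = 0,
                          rating_noise_sd = 0, seed = 96)
  brain_occ <- rep(0.2, 6)
  beh <- gen_behaviour(cfg, brain_occ)
  labs <- beh$labels
  g <- ifelse(labs$label == "happy", 1, ifelse(labs$label == "sad", -1, 0))
  for (i in 1:6) {
    x <- beh$ratings$rating[beh$ratings$subject_id == sprintf("sub%03d", i)]
    expect_equal(emotion_std(x), beh$amp[i] * oracle_std(g), tolerance = 1e-9)
  }
})

test_that("b_true = 0 plants no anhedonia-blunting association", {
  set.seed(97)
  rs <- sapply(1:25, function(i) {
    cfg <- generator_config(n_subjects = 31, n_rois = 21, n_volumes = 250,
                            b_true = 0, seed = 9000 + i)
    occ <- runif(31, 0.1, 0.3)
    beh <- suppressWarnings(gen_behaviour(cfg, occ))
    labs <- beh$labels
    std <- tapply(beh$ratings$rating, beh$ratings$subject_id, emotion_std)
    cor(beh$meta$masq_ad, std[beh$meta$subject_id])
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("the truth manifest round-trips through disk", {
  co <- cached_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$truth$a_true, co$truth$a_true)
  expect_equal(back$truth$ab_true, co$truth$ab_true)
  expect_equal(back$truth$states$sub001, co$truth$states$sub001)
  expect_equal(as.data.frame(back$truth$occupancy),
               as.data.frame(co$truth$occupancy), tolerance = 1e-12)
  expect_equal(back$timeseries$sub001, co$timeseries$sub001,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a cohort directory with missing ratings fails loudly", {
  co <- cached_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  file.remove(file.path(dir, "ratings", "sub003.tsv"))
  expect_error(read_cohort(dir), "sub003")
})
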