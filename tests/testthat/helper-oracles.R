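# Independent oracles used across the suite. These are deliberately
# written as direct transcriptions of the definitions, not as calls into
# the package.

oracle_std <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / length(x))

oracle_rmssd <- function(x) {
  n <- length(x)
  sqrt(sum((x[2:n] - x[1:(n - 1)])^2) / (n - 1))
}

# BH step-up by brute force: largest i with p_(i) <= i*q/m
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  reject
}

# partial correlation via the inverse of the joint correlation matrix —
# a different algebraic route than residualisation
oracle_partial_r <- function(x, y, covs) {
  m <- cbind(x, y, covs)
  pr <- solve(stats::cor(m))
  -pr[1, 2] / sqrt(pr[1, 1] * pr[2, 2])
}

table1 <- function() {
  parse_schedule(read_schedule(leidamood_example("stimulus_schedule.tsv")))
}

# small cohort shared by several tests; cached per test run
cached_cohort <- local({
  cache <- new.env()
  function(seed = 303, n_subjects = 12, n_rois = 63, n_volumes = 150) {
    key <- paste(seed, n_subjects, n_rois, n_volumes, sep = "_")
    if (is.null(cache[[key]])) {
      cfg <- generator_config(n_subjects = n_subjects, n_rois = n_rois,
                              n_volumes = n_volumes, seed = seed)
      cache[[key]] <- suppressWarnings(simulate_cohort(cfg))
    }
    cache[[key]]
  }
})
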