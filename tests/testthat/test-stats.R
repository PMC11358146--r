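test_that("partial correlation without covariates reduces to plain Pearson", {
  d <- tibble::tibble(x = 1:20, y = 2 * (1:20) + 1)
  res <- partial_pearson(d, "x", "y")
  expect_equal(res$r, 1, tolerance = 1e-12)
  set.seed(81)
  d2 <- tibble::tibble(x = rnorm(30), y = rnorm(30))
  expect_equal(partial_pearson(d2, "x", "y")$r, cor(d2$x, d2$y),
               tolerance = 1e-12)
  expect_equal(partial_pearson(d2, "x", "y")$p,
               cor.test(d2$x, d2$y)$p.value, tolerance = 1e-10)
})

test_that("partial correlation matches the inverse-correlation-matrix oracle", {
  set.seed(82)
  for (i in 1:150) {
    n <- sample(15:80, 1)
    q <- sample(1:3, 1)
    covs <- matrix(rnorm(n * q), n)
    d <- tibble::tibble(x = rnorm(n) + covs %*% rnorm(q),
                        y = rnorm(n) + covs %*% rnorm(q))
    d$x <- as.vector(d$x); d$y <- as.vector(d$y)
    for (j in seq_len(q)) d[[paste0("c", j)]] <- covs[, j]
    res <- partial_pearson(d, "x", "y", paste0("c", seq_len(q)))
    expect_equal(res$r, oracle_partial_r(d$x, d$y, covs), tolerance = 1e-10)
  }
})

test_that("partial-correlation p-values are uniform under the null", {
  set.seed(83)
  ps <- replicate(2000, {
    n <- 25
    cv <- rnorm(n)
    d <- tibble::tibble(x = rnorm(n), y = cv + rnorm(n, 0, 1e-8), c1 = cv)
    partial_pearson(d, "x", "y", "c1")$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate designs are rejected", {
  d <- tibble::tibble(x = rnorm(20), y = rnorm(20), c1 = 1:20, c2 = 2 * (1:20))
  expect_error(partial_pearson(d, "x", "y", c("c1", "c2")), "rank-deficient")
  d2 <- tibble::tibble(x = rnorm(20), y = 1:20, c1 = 1:20)
  expect_error(partial_pearson(d2, "x", "y", "c1"), "zero residual variance")
})

test_that("BH rejections follow the step-up rule", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_false(any(fdr_bh(rep(1, 6), q = 0.05)$reject))
  r3 <- fdr_bh(0.04, q = 0.05)
  expect_true(r3$reject)
  expect_equal(r3$p_fdr, 0.04)
  set.seed(84)
  for (i in 1:300) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    got <- fdr_bh(p, q = 0.05)
    expect_identical(got$reject, oracle_bh_reject(p, 0.05))
    # BH rejects at least everything Bonferroni rejects
    expect_true(all(got$reject[p <= 0.05 / m]))
  }
})

test_that("median split puts the median itself in the high group", {
  expect_equal(as.character(median_split(c(30, 34, 40))),
               c("low", "high", "high"))
  expect_true(all(median_split(c(5, 5, 5)) == "high"))
  expect_equal(as.character(median_split(c(1, 2))), c("low", "high"))
})

test_that("an identity chain is collinearity-guarded", {
  x <- rnorm(50)
  d <- tibble::tibble(iv = x, m = x, dv = x)
  f <- mediate(d, "iv", "m", "dv", n_boot = 1000, seed = 1)
  expect_equal(f$a, 1)
  expect_equal(f$b, 1)
  expect_equal(f$ab, 1)
  expect_equal(f$c_prime, 0)
})

test_that("the OLS decomposition c = c_prime + ab is exact", {
  set.seed(85)
  for (i in 1:50) {
    n <- sample(12:200, 1)
    d <- tibble::tibble(iv = rnorm(n), m = rnorm(n), dv = rnorm(n))
    d$m <- d$m + 0.5 * d$iv
    d$dv <- d$dv - 0.3 * d$m + 0.2 * d$iv
    f <- mediate(d, "iv", "m", "dv", n_boot = 1000, seed = i)
    expect_equal(f$c_total, f$c_prime + f$ab, tolerance = 1e-10)
  }
})

test_that("mediation coefficients match lm on z-scores", {
  set.seed(86)
  n <- 120
  d <- tibble::tibble(iv = rnorm(n))
  d$m <- 0.6 * d$iv + rnorm(n)
  d$dv <- -0.4 * d$m + 0.1 * d$iv + rnorm(n)
  f <- mediate(d, "iv", "m", "dv", n_boot = 1000, seed = 2)
  zi <- as.vector(scale(d$iv)); zm <- as.vector(scale(d$m))
  zd <- as.vector(scale(d$dv))
  expect_equal(f$a, unname(coef(lm(zm ~ zi))[2]), tolerance = 1e-10)
  jm <- lm(zd ~ zm + zi)
  expect_equal(f$b, unname(coef(jm)[2]), tolerance = 1e-10)
  expect_equal(f$c_prime, unname(coef(jm)[3]), tolerance = 1e-10)
  expect_equal(f$c_total, unname(coef(lm(zd ~ zi))[2]), tolerance = 1e-10)
  expect_equal(f$p_b, summary(jm)$coefficients[2, 4], tolerance = 1e-8)
})

test_that("the bootstrap is deterministic under a fixed seed", {
  set.seed(87)
  d <- tibble::tibble(iv = rnorm(40), m = rnorm(40), dv = rnorm(40))
  f1 <- mediate(d, "iv", "m", "dv", n_boot = 1000, seed = 9)
  f2 <- mediate(d, "iv", "m", "dv", n_boot = 1000, seed = 9)
  expect_identical(f1$ci_ab, f2$ci_ab)
  expect_identical(f1$ab_boot, f2$ab_boot)
})

test_that("mediation input contracts are enforced", {
  d <- tibble::tibble(iv = rnorm(5), m = rnorm(5), dv = rnorm(5))
  expect_error(mediate(d, "iv", "m", "dv", seed = 1), "at least 10")
  d2 <- tibble::tibble(iv = rnorm(20), m = rnorm(20), dv = rnorm(20))
  expect_error(mediate(d2, "iv", "m", "dv", n_boot = 10, seed = 1),
               "at least 1000")
  expect_error(mediate(dplyr::mutate(d2, m = 1), "iv", "m", "dv", seed = 1),
               "zero variance")
})

test_that("tidy and glance summarise a mediation fit", {
  set.seed(88)
  d <- tibble::tibble(iv = rnorm(40), m = rnorm(40), dv = rnorm(40))
  f <- mediate(d, "iv", "m", "dv", n_boot = 1000, seed = 3)
  td <- tidy(f)
  expect_equal(td$term, c("a", "b", "ab", "c_prime", "c_total"))
  expect_equal(td$estimate[3], f$ab)
  gl <- glance(f)
  expect_equal(gl$n, 40)
  expect_equal(gl$ci_low, f$ci_ab[1])
})
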