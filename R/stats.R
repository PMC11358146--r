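#' Covariate-controlled Pearson correlation
#'
#' Residualises `x` and `y` on the covariates (plus intercept) by least
#' squares and correlates the residuals. The two-sided p-value uses the
#' t reference distribution with `n - 2 - q` degrees of freedom, `q` the
#' number of covariates. Rows with a missing value in any involved
#' column are dropped first (complete cases).
#'
#' @param data A data frame.
#' @param x,y Column names of the two variables of interest.
#' @param covariates Character vector of covariate column names (may be
#'   empty). Factor/character covariates are expanded to dummies.
#' @return A one-row tibble `x, y, covariates, n, r, p`.
#' @export
partial_pearson <- function(data, x, y, covariates = character()) {
  data <- as_tibble(data)
  stopifnot(all(c(x, y, covariates) %in% names(data)))
  data <- data[stats::complete.cases(data[, c(x, y, covariates)]), ]
  n <- nrow(data)
  q0 <- length(covariates)
  if (n <= q0 + 2) abort("need n > q + 2 observations")

  if (q0) {
    f <- stats::as.formula(paste("~", paste(covariates, collapse = "+")))
    z <- stats::model.matrix(f, data = data)
    if (qr(z)$rank < ncol(z)) abort("covariates are rank-deficient")
    q <- ncol(z) - 1L   # dummies count toward the lost df
    rx <- stats::lsfit(z, data[[x]], intercept = FALSE)$residuals
    ry <- stats::lsfit(z, data[[y]], intercept = FALSE)$residuals
  } else {
    q <- 0L
    rx <- data[[x]] - mean(data[[x]])
    ry <- data[[y]] - mean(data[[y]])
  }
  if (sd(rx) <= 1e-10 * max(sd(data[[x]]), 1) ||
      sd(ry) <= 1e-10 * max(sd(data[[y]]), 1)) {
    abort("zero residual variance after removing covariates")
  }
  r <- cor(rx, ry)
  df <- n - 2L - q
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  tibble(x = x, y = y,
         covariates = paste(covariates, collapse = ","),
         n = n, r = r, p = min(p, 1))
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `q`: sort the m p-values ascending, find
#' the largest i with `p_(i) <= i*q/m`, and reject hypotheses 1..i.
#' Adjusted p-values follow the standard monotone min-cummin
#' construction; a hypothesis is rejected iff its adjusted p is <= q.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q Target false-discovery rate, in `(0, 1)`.
#' @return A tibble `p, p_fdr, reject` in the input order.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) abort("`q` must lie in (0, 1)")
  p_fdr <- stats::p.adjust(p, method = "BH")
  tibble(p = p, p_fdr = p_fdr, reject = p_fdr <= q)
}

#' Median-split grouping
#'
#' Splits scores at the sample median: `high` for scores at or above the
#' median, `low` below it.
#'
#' @param scores Numeric vector (length >= 2).
#' @return A factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) abort("need at least 2 scores")
  med <- median(scores)
  factor(ifelse(scores >= med, "high", "low"), levels = c("low", "high"))
}

#' Single-mediator bootstrap mediation analysis
#'
#' Fits the standardized simple mediation model IV -> M -> DV: all three
#' variables are z-scored, `a` is the OLS slope of M on IV, `b` and the
#' direct effect `c'` come from the joint OLS of DV on M and IV, and the
#' total effect `c` from DV on IV alone, so `c = c' + a*b` exactly. The
#' indirect effect `ab = a*b` gets a percentile bootstrap confidence
#' interval from case resampling with replacement. Full mediation is
#' reported when the interval excludes 0, `c` is significant and `c'` is
#' not (at `1 - ci_level`).
#'
#' Degenerate bootstrap resamples (zero variance in any variable) are
#' redrawn and counted; more than 10% redraws is an error.
#'
#' @param data A data frame.
#' @param iv,m,dv Column names of the independent variable, mediator and
#'   dependent variable.
#' @param n_boot Number of bootstrap resamples (>= 1000; default 5000).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap (required).
#' @return An object of class `mediation_fit`; see
#'   [tidy.mediation_fit()] and [glance.mediation_fit()].
#' @export
mediate <- function(data, iv, m, dv, n_boot = 5000, ci_level = 0.95, seed) {
  if (missing(seed)) abort("`seed` is required for a reproducible bootstrap")
  data <- as_tibble(data)
  stopifnot(all(c(iv, m, dv) %in% names(data)))
  n <- nrow(data)
  if (n < 10) abort("need at least 10 cases")
  if (n_boot < 1000) abort("`n_boot` must be at least 1000")
  z <- cbind(iv = data[[iv]], m = data[[m]], dv = data[[dv]])
  if (anyNA(z)) abort("missing values in mediation variables")
  if (any(apply(z, 2, sd) == 0)) abort("zero variance in a mediation variable")
  z <- scale(z)

  est <- med_paths(z)
  p <- med_pvalues(est, n)

  set.seed(derive_seed(seed, 7))
  ab_boot <- numeric(n_boot)
  redraws <- 0L
  max_redraws <- ceiling(0.1 * n_boot)
  i <- 1L
  while (i <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    zb <- z[idx, , drop = FALSE]
    if (any(apply(zb, 2, sd) == 0)) {
      redraws <- redraws + 1L
      if (redraws > max_redraws) abort("too many degenerate bootstrap resamples")
      next
    }
    eb <- med_paths(zb)  # med_paths is correlation-based, hence scale-free
    ab_boot[i] <- eb$a * eb$b
    i <- i + 1L
  }
  alpha <- 1 - ci_level
  ci <- unname(quantile(ab_boot, c(alpha / 2, 1 - alpha / 2)))

  structure(list(
    a = est$a, b = est$b, ab = est$a * est$b,
    c_prime = est$c_prime, c_total = est$c_total,
    p_a = p$p_a, p_b = p$p_b, p_c_prime = p$p_c_prime, p_c_total = p$p_c_total,
    ci_ab = ci, ci_level = ci_level, n = n, n_boot = n_boot, seed = seed,
    n_redraws = redraws, ab_boot = ab_boot,
    full_mediation = (ci[1] > 0 || ci[2] < 0) &&
      p$p_c_total < alpha && p$p_c_prime >= alpha,
    vars = c(iv = iv, m = m, dv = dv)
  ), class = "mediation_fit")
}

# standardized path coefficients from the correlation structure;
# algebraically identical to OLS on the z-scores
med_paths <- function(z) {
  r_im <- cor(z[, 1], z[, 2])
  r_id <- cor(z[, 1], z[, 3])
  r_md <- cor(z[, 2], z[, 3])
  denom <- 1 - r_im^2
  if (denom < 1e-12) {
    # IV and M collinear: the joint regression is unidentified; attribute
    # the shared effect to the mediator path
    return(list(a = r_im, b = r_md, c_prime = 0, c_total = r_id,
                r_im = r_im, r_id = r_id, r_md = r_md, r2 = r_md^2))
  }
  b <- (r_md - r_id * r_im) / denom
  c_prime <- (r_id - r_md * r_im) / denom
  r2 <- (r_id^2 + r_md^2 - 2 * r_id * r_md * r_im) / denom
  list(a = r_im, b = b, c_prime = c_prime, c_total = r_id,
       r_im = r_im, r_id = r_id, r_md = r_md, r2 = r2)
}

med_pvalues <- function(est, n) {
  p_simple <- function(r, df) {
    t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    min(2 * pt(-abs(t), df), 1)
  }
  # joint regression DV ~ M + IV: df = n - 3
  se_scale <- sqrt(pmax(1 - est$r2, .Machine$double.eps) /
                     ((n - 3) * pmax(1 - est$r_im^2, .Machine$double.eps)))
  p_joint <- function(beta) min(2 * pt(-abs(beta / se_scale), n - 3), 1)
  list(
    p_a = p_simple(est$a, n - 2),
    p_b = p_joint(est$b),
    p_c_prime = p_joint(est$c_prime),
    p_c_total = p_simple(est$c_total, n - 2)
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s  (n = %d)\n",
              x$vars["iv"], x$vars["m"], x$vars["dv"], x$n))
  cat(sprintf("  a = %.3f (p = %.4g)   b = %.3f (p = %.4g)\n",
              x$a, x$p_a, x$b, x$p_b))
  cat(sprintf("  indirect ab = %.3f, %d%% bootstrap CI [%.3f, %.3f] (%d resamples)\n",
              x$ab, round(100 * x$ci_level), x$ci_ab[1], x$ci_ab[2], x$n_boot))
  cat(sprintf("  direct c' = %.3f (p = %.4g)   total c = %.3f (p = %.4g)\n",
              x$c_prime, x$p_c_prime, x$c_total, x$p_c_total))
  cat(sprintf("  full mediation: %s\n", x$full_mediation))
  invisible(x)
}

#' Tidy and summarise a mediation fit
#'
#' @param x A `mediation_fit` from [mediate()].
#' @param ... Unused.
#' @return `tidy()`: one row per path (`a`, `b`, `ab`, `c_prime`,
#'   `c_total`) with `estimate`, `p.value`, and CI bounds for `ab`;
#'   `glance()`: one-row fit summary.
#' @method tidy mediation_fit
#' @export
tidy.mediation_fit <- function(x, ...) {
  tibble(
    term = c("a", "b", "ab", "c_prime", "c_total"),
    estimate = c(x$a, x$b, x$ab, x$c_prime, x$c_total),
    p.value = c(x$p_a, x$p_b, NA, x$p_c_prime, x$p_c_total),
    conf.low = c(NA, NA, x$ci_ab[1], NA, NA),
    conf.high = c(NA, NA, x$ci_ab[2], NA, NA)
  )
}

#' @rdname tidy.mediation_fit
#' @method glance mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble(n = x$n, n_boot = x$n_boot, ci_level = x$ci_level,
         ab = x$ab, ci_low = x$ci_ab[1], ci_high = x$ci_ab[2],
         full_mediation = x$full_mediation, n_redraws = x$n_redraws)
}
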