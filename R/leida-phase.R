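#' Instantaneous BOLD phases via the analytic signal
#'
#' Each ROI column is demeaned and Hilbert-transformed (FFT construction
#' of the analytic signal); the instantaneous phase is the argument of
#' the analytic signal, in (-pi, pi]. No temporal filtering or edge
#' tapering is applied; phase estimates near the series edges are less
#' reliable, and downstream accuracy checks exclude the outer 10% of
#' volumes.
#'
#' @param data A T x N numeric matrix (volumes x ROIs), or a data frame
#'   of the same shape (ROI columns).
#' @return A T x N matrix of phases in (-pi, pi], same dimnames.
#' @export
compute_phases <- function(data) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (nrow(x) < 8) abort("need at least 8 volumes to estimate phases")
  if (anyNA(x)) abort("timeseries contains missing values")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(x)[which(sds == 0)[1]] %||% as.character(which(sds == 0)[1])
    abort(sprintf("ROI '%s' has zero variance; cannot define a phase", nm))
  }
  theta <- apply(x, 2, function(col) Arg(analytic_signal(col - mean(col))))
  dimnames(theta) <- dimnames(x)
  theta
}

# Analytic signal z(t) = x(t) + i H[x](t) via the FFT: positive
# frequencies doubled, negative zeroed, DC and Nyquist kept.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Phase-locking matrix at one timepoint
#'
#' Entry (i, j) is `cos(theta_i - theta_j)`: +1 for fully aligned phases,
#' -1 for anti-phase pairs. The matrix is symmetric with unit diagonal
#' and, being the real part of a complex rank-one outer product, has rank
#' at most 2 and nonnegative eigenvalues.
#'
#' @param theta_t Numeric vector of N phases.
#' @return An N x N matrix.
#' @export
phase_locking_matrix <- function(theta_t) {
  theta_t <- as.numeric(theta_t)
  if (length(theta_t) < 2) abort("need at least 2 ROIs")
  a <- cos(theta_t); b <- sin(theta_t)
  m <- tcrossprod(a) + tcrossprod(b)   # cos(ti - tj)
  m
}

#' Leading eigenvector of a symmetric matrix
#'
#' Power iteration (Gershgorin-shifted so the algebraically largest
#' eigenvalue dominates) with a deterministic start vector; a deflated
#' second iteration estimates the runner-up eigenvalue to flag degenerate
#' (multiplicity > 1) tops. The returned vector has unit Euclidean norm
#' and follows the majority-negative sign convention: most elements
#' negative; on a tie, the element sum is made <= 0; if the sum is 0 the
#' first element is forced negative. Under this convention a globally
#' synchronised timepoint yields an all-negative vector.
#'
#' @param m Symmetric numeric matrix.
#' @param check_degenerate Also estimate the second eigenvalue and flag a
#'   (near-)degenerate top eigenvalue (default `TRUE`).
#' @param warm_start Optional unit vector used to start the iteration.
#' @param tol Convergence tolerance on the iterate's direction.
#' @return A list with `vector` (unit eigenvector), `value` (largest
#'   eigenvalue) and `degenerate` (logical, `NA` when not checked).
#' @export
leading_eigenvector <- function(m, check_degenerate = TRUE, warm_start = NULL,
                                tol = 1e-14) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n != ncol(m) || max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    abort("`m` must be a symmetric matrix")
  }
  shift <- max(rowSums(abs(m)))  # Gershgorin bound: m + shift*I is PSD
  v <- warm_start %||% (sin(seq_len(n)) + 0.5)
  v <- v / sqrt(sum(v^2))
  v <- power_iterate(m, shift, v, tol)
  lambda <- drop(crossprod(v, m %*% v))
  # close eigen-gaps stall plain power iteration; polish with a few
  # Rayleigh-quotient iterations until the residual certifies the pair
  scale_m <- max(1, abs(lambda))
  for (it in 1:8) {
    res <- sqrt(sum((m %*% v - lambda * v)^2))
    if (res <= 1e-12 * scale_m) break
    w <- tryCatch(solve(m - (lambda + res * 1e-3) * diag(n), v),
                  error = function(e) NULL)
    if (is.null(w)) break
    v <- w / sqrt(sum(w^2))
    lambda <- drop(crossprod(v, m %*% v))
  }

  degenerate <- NA
  if (isTRUE(check_degenerate)) {
    u0 <- cos(seq_len(n)) + 0.25
    u0 <- u0 - drop(crossprod(v, u0)) * v
    if (sqrt(sum(u0^2)) < 1e-10) u0 <- c(v[-1], -v[1])  # any non-parallel start
    u <- power_iterate(m, shift, u0 / sqrt(sum(u0^2)), tol, deflate = v)
    lambda2 <- drop(crossprod(u, m %*% u))
    degenerate <- (lambda - lambda2) <= 1e-8 * max(1, abs(lambda))
  }

  list(vector = fix_eig_sign(v), value = lambda, degenerate = degenerate)
}

power_iterate <- function(m, shift, v, tol, deflate = NULL, max_iter = 100000L) {
  for (i in seq_len(max_iter)) {
    w <- m %*% v + shift * v
    if (!is.null(deflate)) w <- w - drop(crossprod(deflate, w)) * deflate
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(drop(v))
    w <- drop(w) / nw
    if (1 - abs(sum(w * v)) < tol) { v <- w; break }
    v <- w
  }
  v
}

# majority-negative sign convention with deterministic tie-breaks
fix_eig_sign <- function(v) {
  npos <- sum(v > 0); nneg <- sum(v < 0)
  if (npos > nneg) return(-v)
  if (npos == nneg) {
    s <- sum(v)
    if (s > 0) return(-v)
    if (s == 0 && v[1] > 0) return(-v)
  }
  v
}

#' Leading-eigenvector series for one subject
#'
#' Computes the phase-locking matrix and its leading eigenvector at every
#' volume. Consecutive volumes warm-start each other's power iteration.
#'
#' @param theta A T x N phase matrix from [compute_phases()].
#' @return A list with `v1` (T x N matrix, unit rows) and `eigval`
#'   (length-T vector of top eigenvalues).
#' @export
leading_eigenvectors <- function(theta) {
  theta <- as.matrix(theta)
  tt <- nrow(theta); n <- ncol(theta)
  v1 <- matrix(0, tt, n, dimnames = list(NULL, colnames(theta)))
  eigval <- numeric(tt)
  warm <- NULL
  for (t in seq_len(tt)) {
    e <- leading_eigenvector(phase_locking_matrix(theta[t, ]),
                             check_degenerate = FALSE, warm_start = warm)
    v1[t, ] <- e$vector
    eigval[t] <- e$value
    warm <- e$vector  # power iteration is sign-invariant; direction carries over
  }
  list(v1 = v1, eigval = eigval)
}
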