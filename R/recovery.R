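#' Permutation-matched state assignment accuracy
#'
#' Cluster labels are arbitrary up to permutation; this matches the
#' recovered labelling to the reference one and reports the best
#' achievable agreement. Exact search over all permutations for k <= 8,
#' greedy confusion-matrix matching above.
#'
#' @param assigned,truth Integer sequences of equal length.
#' @param k Number of states.
#' @return Fraction of volumes agreeing under the best label matching.
#' @export
assignment_accuracy <- function(assigned, truth, k) {
  stopifnot(length(assigned) == length(truth))
  conf <- table(factor(assigned, levels = seq_len(k)),
                factor(truth, levels = seq_len(k)))
  conf <- matrix(as.numeric(conf), k, k)
  n <- length(truth)
  if (k <= 8) {
    perms <- all_permutations(k)
    best <- max(vapply(perms, function(p) {
      sum(conf[cbind(seq_len(k), p)])
    }, 1))
  } else {
    best <- 0
    cc <- conf
    for (i in seq_len(k)) {
      idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      best <- best + cc[idx[1], idx[2]]
      cc[idx[1], ] <- -1; cc[, idx[2]] <- -1
    }
  }
  best / n
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[idx]] <- append(p, k, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}
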