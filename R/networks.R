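#' Bonferroni-style alpha for state labelling
#'
#' The per-comparison significance threshold used when matching k states
#' against reference networks: `0.01 / k`.
#'
#' @param k Number of states.
#' @return `0.01 / k`.
#' @export
alpha_for_k <- function(k) {
  assert_scalar_number(k, "k", lower = 1)
  0.01 / k
}

#' Read a reference network membership table
#'
#' Tab-separated text with columns `roi_name, network`, mapping each ROI
#' to one of the seven canonical resting-state networks (visual,
#' somato-motor, dorsal attention, ventral attention, limbic,
#' fronto-parietal, default-mode). The packaged fixture
#' `yeo7_membership_synthetic.tsv` is a synthetic block assignment for
#' the generator's 105 ROI names — it ships for self-contained examples
#' and tests, not as any empirical atlas mapping; supply your own table
#' for real data.
#'
#' @param path File path.
#' @return A tibble `roi_name, network`.
#' @export
read_network_membership <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("roi_name", "network") %in% names(m))) {
    abort("membership file needs columns `roi_name` and `network`")
  }
  m
}

# long membership table -> N x (number of networks) binary matrix
membership_matrix <- function(membership, roi_names) {
  nets <- unique(membership$network)
  m <- matrix(0L, length(roi_names), length(nets),
              dimnames = list(roi_names, nets))
  idx <- match(roi_names, membership$roi_name)
  if (anyNA(idx)) {
    abort(sprintf("ROI '%s' missing from the membership table",
                  roi_names[which(is.na(idx))[1]]))
  }
  m[cbind(seq_along(roi_names), match(membership$network[idx], nets))] <- 1L
  if (any(colSums(m) == 0)) abort("every reference network must be nonempty")
  m
}

#' Label states by reference-network correlation
#'
#' Correlates each state centroid (all N signed elements) with each
#' binary network-membership column (Pearson, two-sided p from the t
#' reference distribution) and flags networks with `p < 0.01/k`. States
#' with no significant network are global-coherence candidates: their
#' eigenvector elements share one sign, so no specific network detaches
#' from the whole-brain mode.
#'
#' @param repertoire A `state_repertoire`, or a k x N centroid matrix.
#' @param membership A membership table (`roi_name, network`) or an
#'   N x M binary matrix with network column names.
#' @return A tibble with one row per state x network: `state, network,
#'   r, p, significant, alpha`, plus attribute `global_coherence`
#'   (integer vector of states with no significant network).
#' @export
label_states <- function(repertoire, membership) {
  centroids <- if (inherits(repertoire, "state_repertoire")) {
    repertoire$centroids
  } else {
    as.matrix(repertoire)
  }
  k <- nrow(centroids)
  roi_names <- colnames(centroids) %||% sprintf("ROI%03d", seq_len(ncol(centroids)))
  mm <- if (is.matrix(membership)) membership else membership_matrix(membership, roi_names)
  if (nrow(mm) != ncol(centroids)) {
    abort("membership rows must match centroid length")
  }
  alpha <- alpha_for_k(k)

  rows <- purrr::map_dfr(seq_len(k), function(s) {
    v <- centroids[s, ]
    if (stats::sd(v) == 0) abort(sprintf("state %d centroid has zero variance", s))
    purrr::map_dfr(colnames(mm), function(net) {
      ct <- stats::cor.test(v, mm[, net], method = "pearson",
                            alternative = "two.sided")
      tibble(state = s, network = net, r = unname(ct$estimate), p = ct$p.value)
    })
  })
  rows$significant <- rows$p < alpha
  rows$alpha <- alpha
  gc_states <- setdiff(seq_len(k), unique(rows$state[rows$significant]))
  attr(rows, "global_coherence") <- as.integer(gc_states)
  rows
}
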