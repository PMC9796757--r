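#' Coverage of an estimated item selection
#'
#' The proportion of truly relevant items recovered,
#' \eqn{\hat p = n_{corr}/n^*} with \eqn{n_{corr} = |A^* \cap \hat A^*|}.
#'
#' @param true_set,est_set Integer item-index sets of equal size `n_star`.
#' @return A proportion in `[0, 1]`.
#' @export
selection_coverage <- function(true_set, est_set) {
  if (length(true_set) != length(est_set)) {
    stop("`true_set` and `est_set` must have the same size (got ",
         length(true_set), " and ", length(est_set), ")", call. = FALSE)
  }
  length(intersect(true_set, est_set)) / length(true_set)
}

#' Normalized consensus footrule distance
#'
#' Footrule distance between the true and estimated consensus rankings,
#' evaluated on the correctly selected items (each shared item contributes
#' the absolute difference between its rank in the true consensus and its
#' rank in the estimated consensus), divided by the number of correctly
#' selected items. `Inf` when no item was correctly selected.
#'
#' @param true_consensus Integer ranks aligned with `true_set`.
#' @param true_set Integer indices of the truly relevant items.
#' @param est_consensus Integer ranks aligned with `est_set`.
#' @param est_set Integer indices of the estimated items.
#' @return A non-negative number, possibly `Inf`.
#' @export
consensus_dnorm <- function(true_consensus, true_set, est_consensus, est_set) {
  shared <- intersect(true_set, est_set)
  n_corr <- length(shared)
  if (n_corr == 0L) return(Inf)
  tr <- true_consensus[match(shared, true_set)]
  er <- est_consensus[match(shared, est_set)]
  sum(abs(tr - er)) / n_corr
}

#' Recovery distance of an estimated selection and consensus
#'
#' \eqn{d_R = d_\tau(\rho_{A^*}, \hat\rho_{A^*}) + (n^* - n_{corr})(n + n^* + 1)/2},
#' where the Kendall distance \eqn{d_\tau} is computed between the relative
#' orders that the two consensus rankings induce on the correctly selected
#' items, and every missed item incurs the additive penalty.
#'
#' @inheritParams consensus_dnorm
#' @param n Total number of items.
#' @return A non-negative number.
#' @export
recovery_distance <- function(true_consensus, true_set, est_consensus, est_set, n) {
  n_star <- length(true_set)
  shared <- intersect(true_set, est_set)
  n_corr <- length(shared)
  penalty <- (n_star - n_corr) * (n + n_star + 1) / 2
  if (n_corr < 2L) return(penalty)
  tr <- rank_vector(true_consensus[match(shared, true_set)])
  er <- rank_vector(est_consensus[match(shared, est_set)])
  kendall_distance(tr, er) + penalty
}

#' Evaluate a posterior summary against the simulation truth
#'
#' Convenience wrapper computing all performance measures of a fitted
#' selection against the generating truth: the number of correctly selected
#' items, the coverage, the normalized consensus footrule distance, the
#' Kendall distance on the recovered items, and the recovery distance.
#'
#' @param truth A `lowbmm_truth` object from a generator.
#' @param summary A `lowbmm_summary` object from [posterior_summary()].
#' @param n Total number of items (defaults to `summary$n`).
#' @return A one-row tibble with columns `n_corr`, `coverage`, `d_norm`,
#'   `d_tau`, `d_recovery`.
#' @export
evaluate_selection <- function(truth, summary, n = summary$n) {
  shared <- intersect(truth$relevant_set, summary$a_hat)
  n_corr <- length(shared)
  d_tau <- if (n_corr >= 2L) {
    kendall_distance(
      rank_vector(truth$consensus[match(shared, truth$relevant_set)]),
      rank_vector(summary$rho_hat[match(shared, summary$a_hat)])
    )
  } else 0L
  tibble::tibble(
    n_corr = n_corr,
    coverage = selection_coverage(truth$relevant_set, summary$a_hat),
    d_norm = consensus_dnorm(truth$consensus, truth$relevant_set,
                             summary$rho_hat, summary$a_hat),
    d_tau = d_tau,
    d_recovery = recovery_distance(truth$consensus, truth$relevant_set,
                                   summary$rho_hat, summary$a_hat, n)
  )
}
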