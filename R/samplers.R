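#' Sample rankings from a Mallows model
#'
#' Draws approximate samples from the footrule Mallows distribution
#' \eqn{P(R | \alpha, \rho_0) \propto \exp\{-(\alpha/m)\, d(R, \rho_0)\}} with a
#' seeded Metropolis chain using leap-and-shift moves. No exact sampler exists
#' for the footrule metric at general dimension, so each draw is taken from a
#' long Metropolis run. The default spacing (200 m moves, i.e. 200 sweeps,
#' between recorded states, after a 1000-sweep burn-in from a uniform random
#' start) is several times the measured integrated autocorrelation time of
#' the chain (roughly 10-45 sweeps across the relevant scale range), so
#' consecutive draws are effectively independent — which the data generators
#' rely on.
#'
#' @param n_samples Number of rankings to draw.
#' @param rho0 Consensus ranking, a permutation of `1:m`.
#' @param alpha Non-negative scale parameter; 0 gives the uniform distribution.
#' @param leap Leap size of the proposal; default `round(m/5)` clipped to
#'   `[1, m - 1]`.
#' @param burnin Number of Metropolis moves discarded before the first draw
#'   (default `1000 * m`).
#' @param thin Number of moves between recorded draws (default `200 * m`).
#' @param seed Optional integer seed.
#' @param init `"random"` (default) to start the chain from a uniform random
#'   permutation, or `"consensus"` to start at `rho0`.
#' @return An `n_samples` x `m` integer matrix; each row is a permutation.
#' @examples
#' sample_mallows(3, 1:5, alpha = 10, seed = 1)
#' @export
sample_mallows <- function(n_samples, rho0, alpha, leap = NULL,
                           burnin = NULL, thin = NULL, seed = NULL,
                           init = c("random", "consensus")) {
  if (length(n_samples) != 1L || is.na(n_samples) || n_samples < 1) {
    stop("`n_samples` must be a positive integer", call. = FALSE)
  }
  if (!is_permutation(rho0)) stop("`rho0` must be a permutation", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be non-negative", call. = FALSE)
  init <- match.arg(init)
  m <- length(rho0)
  if (is.null(leap)) leap <- default_leap(m)
  if (is.null(burnin)) burnin <- 1000L * m
  if (is.null(thin)) thin <- 200L * m
  if (!is.null(seed)) set.seed(seed)
  .sample_mallows_cpp(as.integer(rho0), alpha, as.integer(n_samples),
                      as.integer(burnin), as.integer(thin), as.integer(leap),
                      init == "random")
}

new_truth <- function(relevant_set, consensus, alpha_true, process, noise_level = 0L) {
  structure(
    list(relevant_set = as.integer(relevant_set),
         consensus = as.integer(consensus),
         alpha_true = alpha_true,
         process = process,
         noise_level = as.integer(noise_level)),
    class = "lowbmm_truth"
  )
}

#' @export
print.lowbmm_truth <- function(x, ...) {
  cat("Synthetic truth (", x$process, " process)\n", sep = "")
  cat("  relevant items:", paste(x$relevant_set, collapse = " "), "\n")
  cat("  consensus ranks:", paste(x$consensus, collapse = " "), "\n")
  cat("  alpha:", x$alpha_true, " noise level:", x$noise_level, "\n")
  invisible(x)
}

sim_checks <- function(n, n_star, N, alpha) {
  if (n_star < 1 || n_star > n) {
    stop("`n_star` must satisfy 1 <= n_star <= n (got n_star = ", n_star,
         ", n = ", n, ")", call. = FALSE)
  }
  if (N < 1) stop("`N` must be at least 1", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be non-negative", call. = FALSE)
}

#' Simulate rank data from the top-rank process
#'
#' Generates complete rankings in which a random subset of `n_star` relevant
#' items occupies the top ranks `1:n_star` according to a Mallows draw around
#' the consensus `(1, ..., n_star)`, while the remaining items are assigned a
#' uniform random permutation of the bottom ranks `(n_star + 1):n`. The
#' relevant subset is a seeded random relabelling of the items, so selection
#' methods cannot exploit index order.
#'
#' @param n Total number of items.
#' @param n_star Number of relevant (Mallows-distributed) items.
#' @param N Number of assessors (rows).
#' @param alpha Mallows scale parameter of the relevant block.
#' @param seed Optional integer seed.
#' @param item_labels Optional character vector of length `n`.
#' @return A list with elements `rankings` (an `N` x `n` integer matrix with
#'   item labels as column names) and `truth` (a `lowbmm_truth` object holding
#'   the relevant set, its consensus ranks, and `alpha`).
#' @examples
#' sim <- simulate_toprank(n = 10, n_star = 4, N = 5, alpha = 10, seed = 1)
#' sim$rankings
#' @export
simulate_toprank <- function(n, n_star, N, alpha, seed = NULL, item_labels = NULL) {
  sim_checks(n, n_star, N, alpha)
  if (!is.null(seed)) set.seed(seed)
  shuffled <- sample.int(n)
  relevant <- shuffled[seq_len(n_star)]
  rest <- shuffled[-seq_len(n_star)]
  rel_draws <- sample_mallows(N, seq_len(n_star), alpha)
  rankings <- matrix(0L, N, n)
  for (j in seq_len(N)) {
    rankings[j, relevant] <- rel_draws[j, ]
    if (n_star < n) {
      rankings[j, rest] <- n_star + sample.int(n - n_star)
    }
  }
  storage.mode(rankings) <- "integer"
  colnames(rankings) <- item_labels %||% paste0("item", seq_len(n))
  list(rankings = rankings,
       truth = new_truth(relevant, seq_len(n_star), alpha, "top_rank"))
}

#' Simulate rank data from the rank-consistency process
#'
#' The `n_star` relevant items keep a Mallows-consistent *relative* order
#' across assessors, but occupy arbitrary absolute rank positions: per
#' assessor, a relative order is drawn from a Mallows model in dimension
#' `n_star`, `n_star` rank positions are drawn uniformly without replacement
#' from `1:n`, and the relevant items are placed on those positions so that
#' their relative order equals the draw. Remaining items receive the leftover
#' ranks uniformly at random.
#'
#' @inheritParams simulate_toprank
#' @return Same structure as [simulate_toprank()].
#' @examples
#' sim <- simulate_rankconsistency(n = 10, n_star = 4, N = 5, alpha = 10, seed = 1)
#' @export
simulate_rankconsistency <- function(n, n_star, N, alpha, seed = NULL,
                                     item_labels = NULL) {
  sim_checks(n, n_star, N, alpha)
  if (!is.null(seed)) set.seed(seed)
  shuffled <- sample.int(n)
  relevant <- shuffled[seq_len(n_star)]
  rel_draws <- sample_mallows(N, seq_len(n_star), alpha)
  rankings <- matrix(0L, N, n)
  for (j in seq_len(N)) {
    positions <- sort(sample.int(n, n_star))
    rankings[j, relevant] <- positions[rel_draws[j, ]]
    leftover <- setdiff(seq_len(n), positions)
    if (length(leftover)) {
      rankings[j, setdiff(seq_len(n), relevant)] <- sample(leftover)
    }
  }
  storage.mode(rankings) <- "integer"
  colnames(rankings) <- item_labels %||% paste0("item", seq_len(n))
  list(rankings = rankings,
       truth = new_truth(relevant, seq_len(n_star), alpha, "rank_consistency"))
}

#' Perturb simulated rank data by iterative rank swapping
#'
#' Robustness perturbation: at level 1 the relevant item with true consensus
#' rank `n_star` (the bottom of the relevant block) has its rank swapped with
#' that of an item outside the true set, for a uniformly chosen subset of
#' `ceiling(fraction * N)` assessors; level `i` repeats this for the item with
#' true consensus rank `n_star - i + 1`, drawing a fresh outside item (without
#' replacement across levels) and a fresh assessor subset.
#'
#' @param rankings Rank matrix produced by a generator.
#' @param truth The matching `lowbmm_truth` object.
#' @param levels Number of swap levels (0 returns the input unchanged).
#' @param fraction Fraction of assessors perturbed per level (default 0.9).
#' @param seed Optional integer seed.
#' @return The perturbed rank matrix.
#' @export
add_swap_noise <- function(rankings, truth, levels, fraction = 0.9, seed = NULL) {
  rankings <- assert_rank_matrix(rankings)
  n_star <- length(truth$relevant_set)
  if (levels < 0 || levels > n_star) {
    stop("`levels` must be between 0 and n_star = ", n_star, call. = FALSE)
  }
  if (fraction < 0 || fraction > 1) stop("`fraction` must be in [0, 1]", call. = FALSE)
  if (levels == 0L) return(rankings)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(rankings)
  n <- ncol(rankings)
  outside_pool <- setdiff(seq_len(n), truth$relevant_set)
  outside_items <- sample(outside_pool, levels)
  n_hit <- ceiling(fraction * N)
  for (i in seq_len(levels)) {
    target_rank <- n_star - i + 1L
    item_in <- truth$relevant_set[which(truth$consensus == target_rank)]
    item_out <- outside_items[i]
    rows <- sample.int(N, n_hit)
    tmp <- rankings[rows, item_in]
    rankings[rows, item_in] <- rankings[rows, item_out]
    rankings[rows, item_out] <- tmp
  }
  rankings
}

`%||%` <- function(a, b) if (is.null(a)) b else a
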