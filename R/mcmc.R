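#' Sampler settings for the lower-dimensional Bayesian Mallows model
#'
#' Collects and validates the tuning parameters of the two-block
#' Metropolis-Hastings sampler. Defaults follow the recommendations that work
#' well across simulation settings: swap one item of the selected subset per
#' iteration (`swap_L = 1`) and use a leap size of `round(n_star/5)` for the
#' consensus proposal, clipped to its admissible range.
#'
#' @param n_star Assumed number of relevant items.
#' @param alpha Fixed (known or pre-tuned) Mallows scale parameter.
#' @param leap_l Leap size of the consensus proposal, in `1:(n_star - 1)`.
#' @param swap_L Number of items swapped per subset proposal, in `1:n_star`.
#' @param iterations Total MCMC iterations per chain.
#' @param burnin Iterations discarded per chain (default `iterations / 10`).
#' @param thin Keep every `thin`-th post-burn-in state.
#' @param chains Number of independent chains; chain `c` uses `seed + c - 1`.
#' @param seed Optional integer seed.
#' @param init `"mean_rank"` (default) starts every chain from the
#'   data-informed state whose subset holds the `n_star` items with the
#'   smallest mean observed rank, ordered by mean rank; `"random"` starts
#'   from a uniform random subset and consensus. The stationary distribution
#'   is unaffected; the informed start removes the subset-import transient,
#'   which matters when the iteration budget is small relative to
#'   `n_star * (n - n_star)` (single-swap proposals import one item at a
#'   time).
#' @return A `lowbmm_control` list.
#' @export
lowbmm_control <- function(n_star, alpha, leap_l = NULL, swap_L = 1L,
                           iterations = 5000L, burnin = NULL, thin = 1L,
                           chains = 1L, seed = NULL,
                           init = c("mean_rank", "random")) {
  init <- match.arg(init)
  n_star <- as.integer(n_star)
  if (is.na(n_star) || n_star < 1L) stop("`n_star` must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) stop("`iterations` must be positive", call. = FALSE)
  if (is.null(burnin)) burnin <- iterations %/% 10L
  burnin <- as.integer(burnin)
  if (burnin < 0L || burnin >= iterations) {
    stop("`burnin` must satisfy 0 <= burnin < iterations", call. = FALSE)
  }
  if (is.null(leap_l)) leap_l <- default_leap(n_star)
  leap_l <- as.integer(leap_l)
  if (n_star >= 2L && (leap_l < 1L || leap_l > n_star - 1L)) {
    stop("`leap_l` must be in 1:(n_star - 1)", call. = FALSE)
  }
  swap_L <- as.integer(swap_L)
  if (swap_L < 1L || swap_L > n_star) stop("`swap_L` must be in 1:n_star", call. = FALSE)
  thin <- as.integer(thin)
  if (thin < 1L) stop("`thin` must be at least 1", call. = FALSE)
  chains <- as.integer(chains)
  if (chains < 1L) stop("`chains` must be at least 1", call. = FALSE)
  structure(
    list(n_star = n_star, alpha = alpha, leap_l = leap_l, swap_L = swap_L,
         iterations = iterations, burnin = burnin, thin = thin,
         chains = chains, seed = seed, init = init),
    class = "lowbmm_control"
  )
}

#' Fit the lower-dimensional Bayesian Mallows model
#'
#' Runs the two-block Metropolis-Hastings sampler targeting the joint
#' posterior of the consensus ranking \eqn{\rho} (a permutation of
#' `1:n_star`) and the relevant item subset \eqn{A^*} (an `n_star`-subset of
#' the `n` items), under the model in which the data restricted to \eqn{A^*}
#' follow a footrule Mallows distribution with fixed scale `alpha` and the
#' remaining items are uniform noise. Each iteration first updates
#' \eqn{\rho} with a leap-and-shift proposal (Metropolis-Hastings with the
#' exact proposal-mass correction), then updates \eqn{A^*} by swapping
#' `swap_L` items with the complement and reassigning the vacated consensus
#' ranks to the incoming items uniformly at random (a symmetric joint
#' proposal, accepted with the bare likelihood ratio).
#'
#' When `n_star == n` the subset is fixed and the sampler reduces to the
#' full-dimensional Bayesian Mallows model with fixed `alpha`.
#'
#' @param data Rank matrix (assessors x items): a matrix or data frame whose
#'   rows are permutations of `1:n`.
#' @param n_star,alpha,... Passed to [lowbmm_control()] unless `control` is
#'   given.
#' @param control A `lowbmm_control` object; overrides `n_star`, `alpha`, `...`.
#' @return A `lowbmm` fit object with post-burn-in samples `rho_samples` and
#'   `aset_samples` (aligned M' x `n_star` matrices: `aset_samples[m, k]` is an
#'   item index and `rho_samples[m, k]` its consensus rank in sample `m`),
#'   the chain index of every sample, per-chain acceptance rates, and the
#'   settings used. Use [posterior_summary()], [tidy()], [glance()] and
#'   [autoplot()] on it.
#' @examples
#' sim <- simulate_toprank(n = 12, n_star = 4, N = 20, alpha = 10, seed = 1)
#' fit <- lowbmm(sim$rankings, n_star = 4, alpha = 10, iterations = 2000, seed = 1)
#' posterior_summary(fit)
#' @export
lowbmm <- function(data, n_star, alpha, ..., control = NULL) {
  data <- assert_rank_matrix(data)
  n <- ncol(data)
  if (is.null(control)) control <- lowbmm_control(n_star, alpha, ...)
  if (!inherits(control, "lowbmm_control")) {
    stop("`control` must come from lowbmm_control()", call. = FALSE)
  }
  if (control$n_star > n) {
    stop("`n_star` (", control$n_star, ") exceeds the number of items (", n, ")",
         call. = FALSE)
  }
  if (identical(control$init, "mean_rank")) {
    mr <- colMeans(data)
    init_aset <- order(mr, seq_len(n))[seq_len(control$n_star)]
    init_rho <- as.integer(rank(mr[init_aset], ties.method = "first"))
  } else {
    init_aset <- integer(0)
    init_rho <- integer(0)
  }
  rho_all <- list()
  aset_all <- list()
  chain_id <- list()
  acc_rho <- numeric(control$chains)
  acc_set <- numeric(control$chains)
  for (ch in seq_len(control$chains)) {
    if (!is.null(control$seed)) set.seed(control$seed + ch - 1L)
    res <- .run_lowbmm_cpp(data, control$n_star, control$alpha, control$leap_l,
                           control$swap_L, control$iterations, control$burnin,
                           control$thin, as.integer(init_aset),
                           as.integer(init_rho))
    rho_all[[ch]] <- res$rho
    aset_all[[ch]] <- res$aset
    chain_id[[ch]] <- rep(ch, nrow(res$rho))
    acc_rho[ch] <- res$accept_rho
    acc_set[ch] <- res$accept_set
  }
  structure(
    list(rho_samples = do.call(rbind, rho_all),
         aset_samples = do.call(rbind, aset_all),
         chain = unlist(chain_id),
         accept_rho = acc_rho,
         accept_set = acc_set,
         n = n,
         n_star = control$n_star,
         alpha = control$alpha,
         item_labels = colnames(data),
         control = control,
         call = match.call()),
    class = "lowbmm"
  )
}

#' @export
print.lowbmm <- function(x, ...) {
  cat("Lower-dimensional Bayesian Mallows model fit\n")
  cat("  items: ", x$n, "  selected subset size: ", x$n_star,
      "  alpha: ", x$alpha, "\n", sep = "")
  cat("  kept samples: ", nrow(x$rho_samples), " (", x$control$chains,
      " chain", if (x$control$chains > 1) "s", ", ",
      x$control$iterations, " iterations, burn-in ", x$control$burnin,
      ", thin ", x$control$thin, ")\n", sep = "")
  cat("  acceptance rates: rho ", paste(round(x$accept_rho, 3), collapse = "/"),
      ", subset ", paste(round(x$accept_set, 3), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Leap-and-shift proposal for a consensus ranking
#'
#' Moves one uniformly chosen element of `rho` to a new rank drawn uniformly
#' within `l` of its current rank, shifting intervening elements by one. The
#' returned log proposal masses sum, over *all* generating (element, rank)
#' pairs, the probability `(1/m) * (1/|S|)` of producing the move; an
#' adjacent transposition has two generating pairs, any longer move one.
#'
#' @param rho Integer permutation of `1:m`.
#' @param l Leap size, in `1:(m - 1)`.
#' @return A list with `rho_prime`, `log_forward`, `log_backward`.
#' @export
leap_and_shift <- function(rho, l) {
  if (!is_permutation(rho)) stop("`rho` must be a permutation", call. = FALSE)
  m <- length(rho)
  if (l < 1 || l > m - 1) stop("`l` must be in 1:(m - 1)", call. = FALSE)
  .leap_and_shift_cpp(as.integer(rho), as.integer(l))[c("rho_prime",
                                                        "log_forward",
                                                        "log_backward")]
}

#' Acceptance probability of a consensus update
#'
#' @param delta_d Change in the total restricted footrule distance,
#'   \eqn{\sum_j d(R_j, \rho') - \sum_j d(R_j, \rho)}.
#' @param log_forward,log_backward Log proposal masses from [leap_and_shift()].
#' @param alpha Scale parameter.
#' @param n_star Dimension of the consensus.
#' @return The Metropolis-Hastings acceptance probability in (0, 1].
#' @export
accept_rho <- function(delta_d, log_forward, log_backward, alpha, n_star) {
  min(1, exp(log_backward - log_forward - (alpha / n_star) * delta_d))
}

#' Symmetric subset-swap proposal
#'
#' Swaps `L` uniformly chosen items of the current subset with `L` uniformly
#' chosen items of its complement, and reassigns the consensus ranks vacated
#' by the outgoing items to the incoming items uniformly at random. Surviving
#' items keep their ranks.
#'
#' @param aset Integer vector of `n_star` distinct item indices.
#' @param rho Integer permutation of `1:n_star`, aligned with `aset`.
#' @param n Total number of items.
#' @param L Number of items to swap, in `1:n_star`; requires `n_star < n`.
#' @return A list with `aset_prime` and `rho_prime` (aligned as the input).
#' @export
propose_set <- function(aset, rho, n, L = 1L) {
  n_star <- length(aset)
  if (n_star >= n) stop("subset swap requires n_star < n", call. = FALSE)
  if (L < 1 || L > n_star) stop("`L` must be in 1:n_star", call. = FALSE)
  out_pos <- sample.int(n_star, L)
  incoming <- sample(setdiff(seq_len(n), aset), L)
  aset_prime <- aset
  aset_prime[out_pos] <- incoming
  rho_prime <- rho
  rho_prime[out_pos] <- rho[out_pos][sample.int(L)]
  list(aset_prime = aset_prime, rho_prime = rho_prime)
}

#' Acceptance probability of a subset update
#'
#' The subset proposal is symmetric and the priors uniform, so the
#' Metropolis-Hastings ratio reduces to the likelihood ratio.
#'
#' @inheritParams accept_rho
#' @return The acceptance probability in (0, 1].
#' @export
accept_set <- function(delta_d, alpha, n_star) {
  min(1, exp(-(alpha / n_star) * delta_d))
}

#' Total subset footrule distance of a state
#'
#' Reference computation of the sampler's target exponent (up to the factor
#' \eqn{-\alpha/n^*}): \eqn{\sum_j d_{A^*}(R_j, \rho) = \sum_j \sum_{i \in A^*}
#' |R_{ji} - \rho(i)|}, comparing the observed (absolute) ranks of the
#' selected items with the consensus ranks `1:n_star`. Anchoring the
#' consensus to the absolute ranks is what makes the selection informative:
#' an item parked at the bottom of the full ranking cannot masquerade as a
#' well-ranked member of the subset, which it could if the data were
#' re-labelled to a relative order before measuring the distance. Used by
#' tests and the enumeration oracle; the compiled sampler computes the same
#' quantity internally.
#'
#' @param data Rank matrix.
#' @param aset Item subset.
#' @param rho Consensus permutation aligned with `aset`.
#' @return Integer total distance.
#' @export
total_restricted_distance <- function(data, aset, rho) {
  sum(vapply(seq_len(nrow(data)), function(j) {
    sum(abs(data[j, aset] - rho))
  }, numeric(1)))
}
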