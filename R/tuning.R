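#' Mean pairwise footrule distance between assessors
#'
#' \eqn{\bar d = \frac{1}{N(N-1)} \sum_j \sum_{k \ne j} d(R_j, R_k)}: the
#' average footrule distance over ordered pairs of rows, equal to the mean of
#' the unordered pairwise distances.
#'
#' @param rankings Rank matrix (assessors x items), at least two rows.
#' @return A non-negative number.
#' @export
mean_pairwise_distance <- function(rankings) {
  rankings <- assert_rank_matrix(rankings)
  if (nrow(rankings) < 2L) {
    stop("at least two assessors are needed for a pairwise distance", call. = FALSE)
  }
  mean(dist(rankings, method = "manhattan"))
}

#' Off-line estimation of the Mallows scale parameter
#'
#' Matches the observed mean pairwise distance between assessors against the
#' mean pairwise distance of datasets simulated from the Mallows model over a
#' grid of candidate scale values: for each grid value `alpha0`,
#' `reps_per_point` datasets of the same shape as `rankings` are drawn (the
#' consensus used for simulation is irrelevant by right-invariance) and their
#' mean pairwise distances averaged, giving a decreasing curve; the estimate
#' `alpha_hat_n` is the abscissa where linear interpolation of the curve
#' crosses the observed value. By default the bracketing grid interval is
#' then refined with a second, linear grid pass. When `n_star` is supplied,
#' the full-dimension estimate is rescaled to the model dimension with
#' [rescale_alpha()].
#'
#' @param rankings Rank matrix (assessors x items).
#' @param grid Increasing vector of candidate `alpha0` values (at least 2);
#'   default: 12 points geometric on `[0.01, 100]`.
#' @param reps_per_point Simulated datasets per grid value (default 10).
#' @param n_star Optional model dimension for rescaling.
#' @param seed Optional integer seed.
#' @param refine Refine the bracketing interval with a second pass (default
#'   `TRUE`).
#' @param refine_points Grid size of the refinement pass (default 8).
#' @return A `lowbmm_alpha` object: the simulated `curve` (tibble with
#'   `alpha0`, `mean_dist`, `stage`), `data_mean_dist`, `alpha_hat_n`, and —
#'   when `n_star` is given — `alpha_hat_nstar`, plus the maximal footrule
#'   distances used in the rescaling.
#' @export
estimate_alpha <- function(rankings, grid = NULL, reps_per_point = 10L,
                           n_star = NULL, seed = NULL, refine = TRUE,
                           refine_points = 8L) {
  rankings <- assert_rank_matrix(rankings)
  N <- nrow(rankings)
  n <- ncol(rankings)
  if (is.null(grid)) grid <- exp(seq(log(0.01), log(100), length.out = 12L))
  if (length(grid) < 2L || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing with at least 2 points", call. = FALSE)
  }
  if (reps_per_point < 1L) stop("`reps_per_point` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  dbar <- mean_pairwise_distance(rankings)

  simulate_curve <- function(alphas) {
    vapply(alphas, function(a0) {
      mean(vapply(seq_len(reps_per_point), function(r) {
        mean_pairwise_distance(sample_mallows(N, seq_len(n), a0))
      }, numeric(1)))
    }, numeric(1))
  }
  crossing <- function(alphas, curve) {
    sgn <- curve - dbar
    hit <- which(sgn[-length(sgn)] * sgn[-1L] <= 0)
    if (!length(hit)) {
      stop("the observed mean distance (", signif(dbar, 6),
           ") lies outside the simulated curve range [",
           signif(min(curve), 6), ", ", signif(max(curve), 6),
           "]; extend the grid", call. = FALSE)
    }
    i <- hit[1L]
    if (curve[i] == curve[i + 1L]) return(list(i = i, alpha = alphas[i]))
    w <- (curve[i] - dbar) / (curve[i] - curve[i + 1L])
    list(i = i, alpha = alphas[i] + w * (alphas[i + 1L] - alphas[i]))
  }

  curve1 <- simulate_curve(grid)
  cr <- crossing(grid, curve1)
  alpha_hat <- cr$alpha
  curve_tbl <- tibble::tibble(alpha0 = grid, mean_dist = curve1, stage = "coarse")

  if (isTRUE(refine)) {
    sub <- seq(grid[cr$i], grid[cr$i + 1L], length.out = max(3L, refine_points))
    curve2 <- simulate_curve(sub)
    cr2 <- tryCatch(crossing(sub, curve2), error = function(e) NULL)
    if (!is.null(cr2)) alpha_hat <- cr2$alpha
    curve_tbl <- dplyr::bind_rows(
      curve_tbl,
      tibble::tibble(alpha0 = sub, mean_dist = curve2, stage = "refine")
    )
  }

  structure(
    list(curve = curve_tbl,
         data_mean_dist = dbar,
         alpha_hat_n = alpha_hat,
         alpha_hat_nstar = if (!is.null(n_star)) rescale_alpha(alpha_hat, n, n_star),
         n = n, N = N, n_star = n_star,
         maxd_n = max_footrule(n),
         maxd_nstar = if (!is.null(n_star)) max_footrule(n_star)),
    class = "lowbmm_alpha"
  )
}

#' @export
print.lowbmm_alpha <- function(x, ...) {
  cat("Off-line Mallows scale estimate (n = ", x$n, ", N = ", x$N, ")\n", sep = "")
  cat("  observed mean pairwise distance:", signif(x$data_mean_dist, 6), "\n")
  cat("  alpha_hat (dimension n):", signif(x$alpha_hat_n, 6), "\n")
  if (!is.null(x$alpha_hat_nstar)) {
    cat("  alpha_hat (rescaled to n_star = ", x$n_star, "): ",
        signif(x$alpha_hat_nstar, 6), "\n", sep = "")
  }
  invisible(x)
}

#' Rescale a full-dimension scale estimate to the model dimension
#'
#' Converts a scale value estimated on complete n-dimensional rankings into
#' the equivalent scale for the n*-dimensional subset model by matching the
#' Mallows exponent terms across dimensions:
#' \deqn{\hat\alpha_{n^*} = \hat\alpha_n \cdot \frac{n}{n^*} \cdot
#'   \frac{\mathrm{maxd}_{n^*}}{\mathrm{maxd}_n},}
#' with `maxd_m = floor(m^2/2)` the maximal footrule distance in dimension m.
#' Since `maxd_m` grows like \eqn{m^2/2}, the factor behaves as
#' \eqn{n^*/n} for large dimensions: the subset model, whose exponent divides
#' by `n_star` instead of `n` and whose distances live on the smaller scale,
#' needs a proportionally smaller scale value.
#'
#' @param alpha_hat_n Scale estimated at full dimension `n`.
#' @param n Full dimension.
#' @param n_star Model (subset) dimension, `1 <= n_star <= n`.
#' @return The rescaled scale value.
#' @examples
#' rescale_alpha(6.45, 150, 50)  # 2.15
#' @export
rescale_alpha <- function(alpha_hat_n, n, n_star) {
  if (n_star < 1 || n_star > n) {
    stop("`n_star` must satisfy 1 <= n_star <= n", call. = FALSE)
  }
  alpha_hat_n * (n / n_star) * (max_footrule(n_star) / max_footrule(n))
}
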