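#' Tidy a lowBMM fit into per-item posterior statistics
#'
#' One row per item: the posterior selection frequency and, for items selected
#' at least once, the mean posterior consensus rank conditional on selection.
#'
#' @param x A `lowbmm` fit.
#' @param ... Unused.
#' @return A tibble with columns `item`, `label`, `selection_frequency`,
#'   `mean_rank`.
#' @method tidy lowbmm
#' @export
tidy.lowbmm <- function(x, ...) {
  M <- nrow(x$aset_samples)
  idx <- as.vector(x$aset_samples)
  rnk <- as.vector(x$rho_samples)
  counts <- tabulate(idx, nbins = x$n)
  sums <- numeric(x$n)
  agg <- rowsum(as.numeric(rnk), idx)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  tibble::tibble(
    item = seq_len(x$n),
    label = x$item_labels,
    selection_frequency = counts / M,
    mean_rank = ifelse(counts > 0, sums / counts, NA_real_)
  )
}

#' One-row overview of a lowBMM fit
#'
#' @param x A `lowbmm` fit.
#' @param ... Unused.
#' @return A one-row tibble with the dimensions, settings, kept sample count
#'   and mean acceptance rates.
#' @method glance lowbmm
#' @export
glance.lowbmm <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_star = x$n_star,
    alpha = x$alpha,
    chains = x$control$chains,
    iterations = x$control$iterations,
    burnin = x$control$burnin,
    n_samples = nrow(x$rho_samples),
    accept_rho = mean(x$accept_rho),
    accept_set = mean(x$accept_set)
  )
}

#' @method tidy lowbmm_summary
#' @export
tidy.lowbmm_summary <- function(x, ...) x$consensus

#' Heatmap of the marginal posterior rank distribution
#'
#' Displays `P(item selected with rank r)` for the items of the highest
#' probability set, ordered on the x-axis by the estimated consensus
#' `rho_hat` — the standard visual check that selected items concentrate on
#' distinct top ranks.
#'
#' @param object A `lowbmm` fit.
#' @param summary Optional matching `lowbmm_summary` (computed if missing).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lowbmm
#' @export
autoplot.lowbmm <- function(object, summary = NULL, ...) {
  if (is.null(summary)) summary <- posterior_summary(object)
  rp <- rank_probabilities(object)
  ord <- c(summary$a_hat[order(summary$rho_hat)],
           setdiff(summary$hps, summary$a_hat))
  rp <- dplyr::filter(rp, .data$item %in% ord)
  rp$label <- factor(object$item_labels[rp$item],
                     levels = object$item_labels[ord])
  ggplot2::ggplot(rp, ggplot2::aes(x = .data$label, y = .data$rank,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "item (ordered by estimated consensus)",
                  y = "consensus rank",
                  fill = "posterior\nprobability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Tuning curve of the off-line scale estimation
#'
#' Simulated mean pairwise distance against the candidate scale (log axis),
#' the observed mean pairwise distance (horizontal line) and the estimate at
#' their intersection (vertical line).
#'
#' @param object A `lowbmm_alpha` object from [estimate_alpha()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lowbmm_alpha
#' @export
autoplot.lowbmm_alpha <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$alpha0, y = .data$mean_dist,
                               colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$data_mean_dist, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$alpha_hat_n, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(alpha[0]),
                  y = "mean pairwise footrule distance",
                  colour = "grid pass") +
    ggplot2::theme_minimal()
}
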