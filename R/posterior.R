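#' Per-item selection indicators and frequencies
#'
#' Builds the M' x n binary selection matrix W (`W[m, i] = 1` when item `i`
#' belongs to the sampled subset in posterior sample `m`) and its column means
#' `w_bar`, the marginal posterior selection frequency of each item. Every row
#' of W sums to `n_star`, hence `sum(w_bar) == n_star`.
#'
#' @param fit A `lowbmm` fit.
#' @return A list with the binary matrix `W` and the numeric vector `w_bar`.
#' @export
selection_frequencies <- function(fit) {
  M <- nrow(fit$aset_samples)
  if (is.null(M) || M == 0L) stop("the fit contains no posterior samples", call. = FALSE)
  n <- fit$n
  W <- matrix(0L, M, n, dimnames = list(NULL, fit$item_labels))
  W[cbind(rep(seq_len(M), ncol(fit$aset_samples)), as.vector(fit$aset_samples))] <- 1L
  list(W = W, w_bar = colMeans(W))
}

# Fast path used by the summaries: selection frequencies without the dense W.
selection_freq_vector <- function(fit) {
  M <- nrow(fit$aset_samples)
  if (is.null(M) || M == 0L) stop("the fit contains no posterior samples", call. = FALSE)
  tabulate(as.vector(fit$aset_samples), nbins = fit$n) / M
}

#' Highest probability set
#'
#' The k items with the largest posterior selection frequencies; ties at the
#' boundary are broken in favour of the lower item index.
#'
#' @param w_bar Numeric vector of selection frequencies (length n).
#' @param k Size of the set, with `n_star <= k <= n`.
#' @param n_star Subset dimension used for validation (optional).
#' @return Integer vector of `k` item indices, ordered by decreasing
#'   selection frequency.
#' @export
highest_probability_set <- function(w_bar, k, n_star = NULL) {
  n <- length(w_bar)
  if (k < 1 || k > n) stop("`k` must be in 1:n", call. = FALSE)
  if (!is.null(n_star) && k < n_star) {
    stop("`k` must be at least n_star = ", n_star, call. = FALSE)
  }
  order(-w_bar, seq_len(n))[seq_len(k)]
}

#' Posterior summaries of the fitted subset and consensus
#'
#' Computes the point summaries of the joint posterior over (consensus,
#' subset): the selection frequencies `w_bar`; the highest probability set
#' (HPS) of the `k` most frequently selected items; for each HPS item the mean
#' posterior rank `x_bar` over the samples in which it was selected; the
#' estimated relevant set `a_hat` (the HPS items whose mean-rank ranking is at
#' most `n_star`) and the estimated consensus `rho_hat` (the ranking of the
#' mean ranks on `a_hat`). Ties in the mean ranks are broken by higher
#' selection frequency, then by lower item index. Optionally also computes,
#' for each item of `a_hat`, the conditional probability of being ranked in
#' the top `top_k` given selection, and thresholds it at `cutoff` to obtain
#' the top-probability selection `a_top`.
#'
#' @param fit A `lowbmm` fit.
#' @param k HPS size, in `n_star:n`; default `n_star`, so that the estimated
#'   set is exactly the `n_star` most frequently selected items and the mean
#'   ranks only determine their ordering. Larger `k` admits items with lower
#'   selection frequency but a favourable mean rank into the candidate pool,
#'   which is useful for exploration but makes the selection sensitive to
#'   rarely-selected items whose few visits happened at good ranks.
#' @param top_k Top-rank threshold K (default `n_star`).
#' @param cutoff Optional probability cut-off c in `[0, 1]` for `a_top`.
#' @return A `lowbmm_summary` object. Its `consensus` element is a tibble
#'   (one row per `a_hat` item, ordered by estimated consensus rank) with the
#'   item index, label, estimated rank, mean posterior rank, selection
#'   frequency and top-`top_k` probability.
#' @export
posterior_summary <- function(fit, k = NULL, top_k = NULL, cutoff = NULL) {
  n <- fit$n
  n_star <- fit$n_star
  M <- nrow(fit$aset_samples)
  if (is.null(M) || M == 0L) stop("the fit contains no posterior samples", call. = FALSE)
  if (is.null(k)) k <- n_star
  if (k < n_star || k > n) stop("`k` must be in n_star:n", call. = FALSE)
  if (is.null(top_k)) top_k <- n_star
  if (top_k < 1 || top_k > n_star) stop("`top_k` must be in 1:n_star", call. = FALSE)

  w_bar <- selection_freq_vector(fit)
  hps <- highest_probability_set(w_bar, k, n_star)

  idx <- as.vector(fit$aset_samples)
  rnk <- as.vector(fit$rho_samples)
  counts <- tabulate(idx, nbins = n)
  sums <- numeric(n)
  agg <- rowsum(as.numeric(rnk), idx)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  x_bar_all <- ifelse(counts > 0, sums / counts, NA_real_)

  never <- hps[counts[hps] == 0L]
  if (length(never)) {
    warning("HPS item(s) never selected in any sample were excluded: ",
            paste(never, collapse = ", "), call. = FALSE)
    hps <- hps[counts[hps] > 0L]
  }
  if (length(hps) < n_star) {
    stop("fewer than n_star HPS items were ever selected; increase iterations",
         call. = FALSE)
  }
  x_bar <- x_bar_all[hps]
  ord <- order(x_bar, -w_bar[hps], hps)
  rank_x <- integer(length(hps))
  rank_x[ord] <- seq_along(hps)
  in_hat <- rank_x <= n_star
  a_hat <- hps[in_hat]
  rho_hat <- rank_x[in_hat]

  sel_top <- idx %in% a_hat
  top_hits <- tabulate(factor(idx[sel_top & rnk <= top_k], levels = a_hat),
                       nbins = length(a_hat))
  topk_prob <- top_hits / counts[a_hat]
  names(topk_prob) <- fit$item_labels[a_hat]

  a_top <- if (!is.null(cutoff)) {
    if (cutoff < 0 || cutoff > 1) stop("`cutoff` must be in [0, 1]", call. = FALSE)
    a_hat[topk_prob > cutoff]
  } else NULL

  o <- order(rho_hat)
  consensus <- tibble::tibble(
    item = a_hat[o],
    label = fit$item_labels[a_hat[o]],
    consensus_rank = rho_hat[o],
    mean_rank = x_bar[in_hat][o],
    selection_frequency = w_bar[a_hat[o]],
    top_k_probability = topk_prob[o]
  )

  structure(
    list(w_bar = stats::setNames(w_bar, fit$item_labels),
         k = k, hps = hps,
         x_bar = stats::setNames(x_bar, fit$item_labels[hps]),
         a_hat = a_hat, rho_hat = rho_hat,
         top_k = top_k, topk_prob = topk_prob,
         cutoff = cutoff, a_top = a_top,
         consensus = consensus,
         n = n, n_star = n_star, n_samples = M,
         item_labels = fit$item_labels),
    class = "lowbmm_summary"
  )
}

#' @export
print.lowbmm_summary <- function(x, ...) {
  cat("lowBMM posterior summary (", x$n_samples, " samples, n = ", x$n,
      ", n_star = ", x$n_star, ", HPS size k = ", x$k, ")\n", sep = "")
  print(x$consensus)
  if (!is.null(x$a_top)) {
    cat("top-probability selection (K = ", x$top_k, ", c = ", x$cutoff, "): ",
        paste(x$item_labels[x$a_top], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Conditional top-K probabilities of selected items
#'
#' For each item of `items`, the probability of being ranked within the top
#' `K` of the consensus, conditional on being in the sampled subset:
#' `#(selected with rank <= K) / #(selected)`. Items never selected get
#' probability 0 with a warning.
#'
#' @param fit A `lowbmm` fit.
#' @param items Integer item indices (typically the estimated set `a_hat`).
#' @param K Top-rank threshold, at most `n_star`.
#' @return A named numeric vector over `items`.
#' @export
topk_probabilities <- function(fit, items, K) {
  if (K < 1 || K > fit$n_star) stop("`K` must be in 1:n_star", call. = FALSE)
  idx <- as.vector(fit$aset_samples)
  rnk <- as.vector(fit$rho_samples)
  counts <- tabulate(idx, nbins = fit$n)[items]
  hits <- tabulate(factor(idx[rnk <= K], levels = items), nbins = length(items))
  if (any(counts == 0L)) {
    warning("item(s) never selected get top-K probability 0: ",
            paste(items[counts == 0L], collapse = ", "), call. = FALSE)
  }
  out <- ifelse(counts > 0L, hits / pmax(counts, 1L), 0)
  stats::setNames(out, fit$item_labels[items])
}

#' Threshold top-K probabilities into a top selection
#'
#' @param topk_prob Named probabilities as returned by [topk_probabilities()],
#'   or the `topk_prob` element of a summary.
#' @param cutoff Lower probability bound c in `[0, 1]`; items with
#'   probability strictly greater than `cutoff` are kept.
#' @return The names (or indices) of the retained items.
#' @export
top_selection <- function(topk_prob, cutoff) {
  if (cutoff < 0 || cutoff > 1) stop("`cutoff` must be in [0, 1]", call. = FALSE)
  keep <- topk_prob > cutoff
  if (!is.null(names(topk_prob))) names(topk_prob)[keep] else which(keep)
}

#' Marginal posterior rank probabilities
#'
#' Long table of `P(item i selected with consensus rank r)` across posterior
#' samples; for each item the probabilities sum to its selection frequency.
#' This is the plot-ready input for posterior heatmaps.
#'
#' @param fit A `lowbmm` fit.
#' @return A tibble with columns `item`, `label`, `rank`, `probability`.
#' @export
rank_probabilities <- function(fit) {
  M <- nrow(fit$aset_samples)
  tab <- table(item = as.vector(fit$aset_samples), rank = as.vector(fit$rho_samples))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  out <- out[out$Freq > 0, ]
  tibble::tibble(
    item = as.integer(out$item),
    label = fit$item_labels[as.integer(out$item)],
    rank = as.integer(out$rank),
    probability = out$Freq / M
  )
}

#' Export posterior summary tables
#'
#' Writes plot-ready TSV tables: the marginal rank-probability table (heatmap
#' data), the selection-frequency table (bar data), the rank trace of the
#' estimated items along kept iterations, the conditional top-K probability
#' table (violin/histogram data), and a JSON file with the point summaries.
#'
#' @param fit A `lowbmm` fit.
#' @param summary A matching `lowbmm_summary`; computed if missing.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, a named list of the written paths.
#' @export
export_summaries <- function(fit, summary = NULL, dir = ".", prefix = "lowbmm") {
  if (is.null(summary)) summary <- posterior_summary(fit)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  path <- function(what, ext = "tsv") file.path(dir, paste0(prefix, "_", what, ".", ext))

  rp <- rank_probabilities(fit)
  readr::write_tsv(rp, path("rank_probabilities"))

  sf <- tibble::tibble(item = seq_len(fit$n), label = fit$item_labels,
                       selection_frequency = as.numeric(summary$w_bar))
  readr::write_tsv(sf, path("selection_frequencies"))

  keep <- fit$aset_samples %in% summary$a_hat
  trace <- tibble::tibble(
    sample = rep(seq_len(nrow(fit$aset_samples)), ncol(fit$aset_samples))[keep],
    chain = rep(fit$chain, ncol(fit$aset_samples))[keep],
    item = as.vector(fit$aset_samples)[keep],
    rank = as.vector(fit$rho_samples)[keep]
  )
  trace <- dplyr::arrange(trace, .data$sample, .data$item)
  readr::write_tsv(trace, path("trace"))

  tk <- tibble::tibble(item = summary$a_hat,
                       label = fit$item_labels[summary$a_hat],
                       K = summary$top_k,
                       probability = as.numeric(summary$topk_prob))
  readr::write_tsv(tk, path("topk_probabilities"))

  js <- list(n = fit$n, n_star = fit$n_star, alpha = fit$alpha,
             k = summary$k, top_k = summary$top_k,
             selected_items = summary$a_hat,
             selected_labels = fit$item_labels[summary$a_hat],
             consensus_rank = summary$rho_hat,
             cutoff = summary$cutoff,
             top_selection = summary$a_top)
  jsonlite::write_json(js, path("summary", "json"), auto_unbox = TRUE, digits = NA)

  invisible(list(rank_probabilities = path("rank_probabilities"),
                 selection_frequencies = path("selection_frequencies"),
                 trace = path("trace"),
                 topk_probabilities = path("topk_probabilities"),
                 summary = path("summary", "json")))
}
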