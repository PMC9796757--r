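# Independent brute-force oracles used to freeze expected values.

# All permutations of 1:m as rows (recursive construction, independent of any
# package code).
all_perms <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(m - 1L)
  out <- matrix(0L, nrow(sub) * m, m)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(m)) {
      out[row, ] <- append(sub[i, ], m, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

# Brute-force discordant pair count.
kendall_brute <- function(a, b) {
  m <- length(a)
  cnt <- 0L
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (sign(a[i] - a[j]) != sign(b[i] - b[j])) cnt <- cnt + 1L
  }
  cnt
}

# Exhaustively normalized joint posterior over all (subset, consensus) states
# for the subset model: P propto exp(-(alpha/n_star) * sum_j sum_{i in A}
# |R_ji - rho(i)|). Returns keys and probabilities; keys use the sorted
# subset with its aligned consensus ranks.
enumerate_posterior <- function(data, n_star, alpha) {
  n <- ncol(data)
  sets <- utils::combn(n, n_star)
  rhos <- all_perms(n_star)
  keys <- character(0)
  logw <- numeric(0)
  for (s in seq_len(ncol(sets))) {
    A <- sets[, s]
    for (r in seq_len(nrow(rhos))) {
      rho <- rhos[r, ]
      d <- sum(vapply(seq_len(nrow(data)),
                      function(j) sum(abs(data[j, A] - rho)), numeric(1)))
      keys <- c(keys, paste(c(A, rho), collapse = "-"))
      logw <- c(logw, -(alpha / n_star) * d)
    }
  }
  w <- exp(logw - max(logw))
  list(keys = keys, prob = w / sum(w))
}

state_key <- function(aset, rho) {
  o <- order(aset)
  paste(c(aset[o], rho[o]), collapse = "-")
}

# Construct a minimal fit object from hand-written samples (for posterior
# summary tests that need exact, hand-computable inputs).
make_fit <- function(rho_samples, aset_samples, n, alpha = 1) {
  n_star <- ncol(rho_samples)
  structure(
    list(rho_samples = rho_samples,
         aset_samples = aset_samples,
         chain = rep(1L, nrow(rho_samples)),
         accept_rho = 0.5, accept_set = 0.5,
         n = n, n_star = n_star, alpha = alpha,
         item_labels = paste0("item", seq_len(n)),
         control = lowbmm_control(n_star, alpha, iterations = 10L, burnin = 0L),
         call = NULL),
    class = "lowbmm"
  )
}
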