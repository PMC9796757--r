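test_that("selection frequencies conserve the subset size", {
  fit <- make_fit(rho_samples = rbind(c(1L, 2L)),
                  aset_samples = rbind(c(1L, 2L)), n = 4)
  sf <- selection_frequencies(fit)
  expect_identical(sf$w_bar, c(item1 = 1, item2 = 1, item3 = 0, item4 = 0))
  expect_identical(rowSums(sf$W), c(2))

  fit2 <- make_fit(rho_samples = rbind(c(1L, 2L), c(1L, 2L)),
                   aset_samples = rbind(c(1L, 2L), c(2L, 3L)), n = 4)
  sf2 <- selection_frequencies(fit2)
  expect_identical(unname(sf2$w_bar), c(0.5, 1, 0.5, 0))
  expect_identical(sum(sf2$w_bar), 2)
})

test_that("the highest probability set keeps the k most selected items", {
  expect_identical(highest_probability_set(c(0.9, 0.1, 0.8, 0.2), 2), c(1L, 3L))
  expect_setequal(highest_probability_set(c(0.9, 0.1, 0.8, 0.2), 4), 1:4)
  # boundary tie goes to the lower item index
  expect_identical(highest_probability_set(c(0.5, 0.3, 0.3, 0.1), 2), c(1L, 2L))
  expect_error(highest_probability_set(c(0.5, 0.5), 3), "k")
})

test_that("a degenerate chain returns its state as the point summary", {
  rho <- rbind(c(2L, 1L, 3L), c(2L, 1L, 3L), c(2L, 1L, 3L))
  aset <- rbind(c(4L, 6L, 2L), c(4L, 6L, 2L), c(4L, 6L, 2L))
  fit <- make_fit(rho, aset, n = 7)
  s <- suppressWarnings(posterior_summary(fit))
  expect_setequal(s$a_hat, c(4L, 6L, 2L))
  expect_identical(s$rho_hat[match(c(4, 6, 2), s$a_hat)], c(2L, 1L, 3L))
})

test_that("hand-built samples reproduce the posterior summary definitions", {
  # three samples at n = 5, n_star = 2:
  #   {1,2} ranks (1,2); {2,3} ranks (1,2); {2,4} ranks (2,1)
  rho <- rbind(c(1L, 2L), c(1L, 2L), c(2L, 1L))
  aset <- rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L))
  fit <- make_fit(rho, aset, n = 5)
  s <- posterior_summary(fit, k = 4)
  expect_equal(unname(s$w_bar), c(1 / 3, 1, 1 / 3, 1 / 3, 0))
  expect_identical(s$hps, c(2L, 1L, 3L, 4L))  # largest w_bar, ties to lower index
  # mean ranks when selected: item1 -> 1, item2 -> 5/3, item3 -> 2, item4 -> 1
  expect_equal(unname(s$x_bar[match(c("item1", "item2", "item3", "item4"),
                                    names(s$x_bar))]),
               c(1, 5 / 3, 2, 1))
  # ranking the mean ranks (ties by higher w_bar then lower index):
  # item1 (1) < item4 (1) < item2 (5/3) < item3 (2) -> a_hat = {1, 4}
  expect_identical(s$a_hat, c(1L, 4L))
  expect_identical(s$rho_hat, c(1L, 2L))
  expect_true(is_permutation(s$rho_hat))
})

test_that("posterior summaries are invariant to sample order", {
  sim <- simulate_toprank(n = 10, n_star = 4, N = 10, alpha = 5, seed = 31)
  fit <- lowbmm(sim$rankings, n_star = 4, alpha = 5, iterations = 1500, seed = 32)
  s1 <- suppressWarnings(posterior_summary(fit))
  perm <- sample(nrow(fit$rho_samples))
  fit$rho_samples <- fit$rho_samples[perm, , drop = FALSE]
  fit$aset_samples <- fit$aset_samples[perm, , drop = FALSE]
  s2 <- suppressWarnings(posterior_summary(fit))
  expect_identical(s1$a_hat, s2$a_hat)
  expect_identical(s1$rho_hat, s2$rho_hat)
  expect_identical(s1$w_bar, s2$w_bar)
})

test_that("top-K probabilities are conditional frequencies with a zero fallback", {
  rho <- rbind(c(1L, 2L), c(1L, 2L), c(2L, 1L), c(1L, 2L))
  aset <- rbind(c(3L, 5L), c(3L, 5L), c(3L, 5L), c(3L, 2L))
  fit <- make_fit(rho, aset, n = 6)
  pk <- topk_probabilities(fit, c(3L, 5L, 2L), K = 1)
  expect_equal(unname(pk["item3"]), 3 / 4)   # rank 1 in samples 1, 2, 4
  expect_equal(unname(pk["item5"]), 1 / 3)   # rank 1 only in sample 3
  expect_equal(unname(pk["item2"]), 0)       # rank 2 in its only selection
  expect_warning(topk_probabilities(fit, c(3L, 6L), K = 1), "never selected")
  # extremes
  fitc <- make_fit(rbind(c(1L, 2L), c(1L, 2L)), rbind(c(9L, 1L), c(9L, 1L)), n = 9)
  expect_equal(unname(topk_probabilities(fitc, 9L, K = 1)), 1)
  expect_equal(unname(topk_probabilities(fitc, 1L, K = 1)), 0)
})

test_that("top selection applies a strict probability cut-off", {
  probs <- c(a = 0.9, b = 0.8, c = 0.3)
  expect_identical(top_selection(probs, 0.77), c("a", "b"))
  expect_identical(top_selection(probs, 0), c("a", "b", "c"))
  expect_identical(top_selection(c(a = 1, b = 0.5), 1), character(0))
})

test_that("rank probabilities sum to the selection frequency per item", {
  sim <- simulate_toprank(n = 8, n_star = 3, N = 10, alpha = 4, seed = 33)
  fit <- lowbmm(sim$rankings, n_star = 3, alpha = 4, iterations = 1200, seed = 34)
  rp <- rank_probabilities(fit)
  w <- lowbmm:::selection_freq_vector(fit)
  agg <- tapply(rp$probability, rp$item, sum)
  expect_equal(as.numeric(agg), unname(w[as.integer(names(agg))]), tolerance = 1e-12)
})

test_that("exported tables round-trip the in-memory summary", {
  dir <- withr::local_tempdir()
  sim <- simulate_toprank(n = 8, n_star = 3, N = 10, alpha = 6, seed = 35)
  fit <- lowbmm(sim$rankings, n_star = 3, alpha = 6, iterations = 1200, seed = 36)
  s <- suppressWarnings(posterior_summary(fit, cutoff = 0.5))
  paths <- export_summaries(fit, s, dir = dir, prefix = "toy")
  expect_true(all(file.exists(unlist(paths))))
  sf <- readr::read_tsv(paths$selection_frequencies, show_col_types = FALSE)
  expect_equal(sf$selection_frequency, unname(s$w_bar))
  js <- jsonlite::read_json(paths$summary, simplifyVector = TRUE)
  expect_identical(as.integer(js$selected_items), s$a_hat)
  expect_identical(as.integer(js$consensus_rank), s$rho_hat)
  rp <- readr::read_tsv(paths$rank_probabilities, show_col_types = FALSE)
  agg <- tapply(rp$probability, rp$item, sum)
  expect_equal(as.numeric(agg), unname(s$w_bar[as.integer(names(agg))]),
               tolerance = 1e-12)
})
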