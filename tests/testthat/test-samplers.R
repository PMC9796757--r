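test_that("sample_mallows collapses to the consensus in the high-concentration limit", {
  draws <- sample_mallows(5, c(3, 1, 4, 2, 5), alpha = 1e6, seed = 1)
  for (k in 1:5) expect_identical(draws[k, ], c(3L, 1L, 4L, 2L, 5L))
})

test_that("sample_mallows is uniform at alpha = 0", {
  set.seed(4)
  draws <- sample_mallows(6000, 1:3, alpha = 0)
  key <- apply(draws, 1, paste, collapse = "")
  freq <- table(factor(key, levels = apply(all_perms(3), 1, paste, collapse = "")))
  p <- as.numeric(freq) / 6000
  se <- sqrt((1 / 6) * (5 / 6) / 6000)
  expect_true(all(abs(p - 1 / 6) < 3 * se))
})

test_that("sample_mallows matches the exactly normalized pmf at m = 4", {
  m <- 4; alpha <- 3; rho0 <- 1:4
  P <- all_perms(m)
  d <- apply(P, 1, function(r) sum(abs(r - rho0)))
  w <- exp(-(alpha / m) * d); w <- w / sum(w)
  set.seed(5)
  draws <- sample_mallows(20000, rho0, alpha)
  key <- apply(draws, 1, paste, collapse = "")
  emp <- as.numeric(table(factor(key, levels = apply(P, 1, paste, collapse = "")))) / 20000
  se <- sqrt(pmax(w * (1 - w), 1e-6) / 20000)
  expect_true(all(abs(emp - w) < 4 * se + 0.002))
})

test_that("mean distance to the consensus is non-increasing in alpha", {
  set.seed(6)
  md <- vapply(c(0, 1, 3, 10), function(a) {
    mean(rowSums(abs(sweep(sample_mallows(400, 1:8, a), 2, 1:8))))
  }, numeric(1))
  expect_true(all(diff(md) < 1))  # allow MC jitter, require clear decrease overall
  expect_lt(md[4], md[1])
})

test_that("top-rank generator yields valid permutations with the relevant block on top", {
  sim <- simulate_toprank(n = 12, n_star = 5, N = 20, alpha = 8, seed = 7)
  expect_true(all(apply(sim$rankings, 1, is_permutation)))
  for (j in 1:20) {
    expect_setequal(sim$rankings[j, sim$truth$relevant_set], 1:5)
  }
  # restricted distances match the Mallows mean at the generating scale
  m <- 8; alpha <- 10
  sim2 <- simulate_toprank(n = 20, n_star = m, N = 400, alpha = alpha, seed = 8)
  obs <- mean(vapply(seq_len(400), function(j) {
    footrule(restrict_ranking(sim2$rankings[j, ], sim2$truth$relevant_set),
             sim2$truth$consensus)
  }, numeric(1)))
  set.seed(9)
  ref <- mean(rowSums(abs(sweep(sample_mallows(400, 1:m, alpha), 2, 1:m))))
  expect_lt(abs(obs - ref), 0.6)
})

test_that("rank-consistency generator preserves relative order, not positions", {
  sim <- simulate_rankconsistency(n = 10, n_star = 4, N = 15, alpha = 1e6, seed = 10)
  expect_true(all(apply(sim$rankings, 1, is_permutation)))
  rel <- t(apply(sim$rankings[, sim$truth$relevant_set], 1, rank))
  for (j in 1:15) expect_identical(as.integer(rel[j, ]), sim$truth$consensus)
  # absolute positions must differ across assessors
  expect_gt(length(unique(apply(sim$rankings[, sim$truth$relevant_set], 1,
                                paste, collapse = "-"))), 1L)
})

test_that("swap noise follows the level schedule and keeps rows valid", {
  sim <- simulate_toprank(n = 12, n_star = 5, N = 10, alpha = 20, seed = 11)
  expect_identical(add_swap_noise(sim$rankings, sim$truth, 0), sim$rankings)

  pert1 <- add_swap_noise(sim$rankings, sim$truth, 1, fraction = 1, seed = 12)
  expect_true(all(apply(pert1, 1, is_permutation)))
  bottom_item <- sim$truth$relevant_set[sim$truth$consensus == 5L]
  changed <- which(colSums(pert1 != sim$rankings) > 0)
  expect_true(bottom_item %in% changed)
  expect_length(changed, 2L)  # the bottom relevant item and one outside item
  other <- setdiff(changed, bottom_item)
  expect_identical(pert1[, bottom_item], sim$rankings[, other])
  expect_identical(pert1[, other], sim$rankings[, bottom_item])

  pert4 <- add_swap_noise(sim$rankings, sim$truth, 4, fraction = 1, seed = 13)
  changed4 <- which(colSums(pert4 != sim$rankings) > 0)
  hit_relevant <- intersect(changed4, sim$truth$relevant_set)
  expect_identical(sort(sim$truth$consensus[match(hit_relevant, sim$truth$relevant_set)]),
                   2:5)  # levels 1..4 hit true ranks 5,4,3,2
  expect_length(setdiff(changed4, sim$truth$relevant_set), 4L)
  expect_error(add_swap_noise(sim$rankings, sim$truth, 6), "levels")
})

test_that("generators are bit-for-bit reproducible under a seed", {
  a <- simulate_toprank(n = 15, n_star = 6, N = 8, alpha = 3, seed = 99)
  b <- simulate_toprank(n = 15, n_star = 6, N = 8, alpha = 3, seed = 99)
  expect_identical(a$rankings, b$rankings)
  expect_identical(a$truth$relevant_set, b$truth$relevant_set)
  c1 <- simulate_rankconsistency(n = 15, n_star = 6, N = 8, alpha = 3, seed = 98)
  c2 <- simulate_rankconsistency(n = 15, n_star = 6, N = 8, alpha = 3, seed = 98)
  expect_identical(c1$rankings, c2$rankings)
  expect_error(simulate_toprank(n = 5, n_star = 6, N = 2, alpha = 1), "n_star")
})
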