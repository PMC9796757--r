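test_that("control settings are validated", {
  expect_error(lowbmm_control(8, 2, iterations = 0), "iterations")
  expect_error(lowbmm_control(8, 2, burnin = 5000), "burnin")
  expect_error(lowbmm_control(8, -1), "alpha")
  expect_error(lowbmm_control(8, 2, leap_l = 8), "leap_l")
  expect_error(lowbmm_control(8, 2, swap_L = 9), "swap_L")
  ctl <- lowbmm_control(8, 2)
  expect_identical(ctl$leap_l, 2L)  # round(n_star / 5), clipped
  expect_identical(ctl$swap_L, 1L)
  expect_identical(ctl$burnin, 500L)
})

test_that("leap-and-shift changes between 2 and l + 1 positions", {
  set.seed(20)
  for (rep in 1:200) {
    m <- sample(3:7, 1)
    l <- sample.int(m - 1, 1)
    rho <- sample.int(m)
    pr <- leap_and_shift(rho, l)
    expect_true(is_permutation(pr$rho_prime))
    nd <- sum(pr$rho_prime != rho)
    expect_gte(nd, 2L)
    expect_lte(nd, l + 1L)
  }
  expect_error(leap_and_shift(1:4, 4), "l")
})

test_that("leap-and-shift transition rows are normalized and reversible", {
  # enumerate the reachable states by exhaustive sampling; the forward masses
  # must sum to one, and the backward mass must equal the forward mass of the
  # reverse move computed from the proposed state
  set.seed(21)
  for (m in 3:5) for (l in 1:2) {
    if (l > m - 1) next
    for (start in 1:3) {
      rho <- sample.int(m)
      seen <- new.env(parent = emptyenv())
      total <- 0
      for (it in 1:1500) {
        pr <- leap_and_shift(rho, l)
        key <- paste(pr$rho_prime, collapse = "")
        if (is.null(seen[[key]])) {
          assign(key, TRUE, envir = seen)
          total <- total + exp(pr$log_forward)
        }
      }
      expect_equal(total, 1, tolerance = 1e-12)
    }
  }
  # reversibility of the proposal masses (adjacent swaps have two generating
  # pairs, longer leaps one)
  set.seed(22)
  for (rep in 1:100) {
    rho <- sample.int(5)
    pr <- leap_and_shift(rho, 2)
    # re-derive the backward mass by brute force: probability that one leap
    # from rho_prime yields rho
    hits <- 0; tries <- 4000
    for (t in seq_len(tries)) {
      back <- leap_and_shift(pr$rho_prime, 2)
      if (all(back$rho_prime == rho)) hits <- hits + 1
    }
    expect_lt(abs(hits / tries - exp(pr$log_backward)),
              4 * sqrt(exp(pr$log_backward) / tries) + 0.01)
  }
})

test_that("acceptance probabilities follow the closed forms", {
  expect_equal(accept_rho(0, log(0.3), log(0.3), 5, 5), 1)
  expect_equal(accept_rho(2, log(0.3), log(0.3), 8, 8), exp(-2))
  expect_equal(accept_rho(-3, log(0.3), log(0.3), 8, 8), 1)
  expect_equal(accept_set(0, 4, 8), 1)
  expect_equal(accept_set(3, 5, 5), exp(-3))
  expect_equal(accept_set(-4, 5, 5), 1)
})

test_that("subset proposal swaps L items and preserves surviving ranks", {
  set.seed(23)
  for (rep in 1:100) {
    n <- 9; n_star <- 4
    aset <- sample.int(n, n_star)
    rho <- sample.int(n_star)
    L <- sample.int(n_star, 1)
    pr <- propose_set(aset, rho, n, L)
    expect_length(setdiff(pr$aset_prime, aset), L)
    expect_length(setdiff(aset, pr$aset_prime), L)
    surv <- which(pr$aset_prime == aset)
    expect_identical(pr$rho_prime[surv], rho[surv])
    expect_true(is_permutation(pr$rho_prime))
  }
  # uniformity of the (out, in) pair at n = 6, n_star = 3, L = 1
  set.seed(24)
  aset <- c(1L, 3L, 5L); rho <- c(2L, 1L, 3L)
  pairs <- replicate(9000, {
    pr <- propose_set(aset, rho, 6, 1)
    paste(setdiff(aset, pr$aset_prime), setdiff(pr$aset_prime, aset))
  })
  freq <- table(pairs) / 9000
  expect_length(freq, 9L)
  expect_true(all(abs(freq - 1 / 9) < 4 * sqrt((1 / 9) * (8 / 9) / 9000)))
  expect_error(propose_set(1:4, 1:4, 4, 1), "n_star < n")
  expect_error(propose_set(1:3, 1:3, 6, 4), "L")
})

test_that("the fitted chain stores valid states and acceptance rates", {
  sim <- simulate_toprank(n = 10, n_star = 4, N = 6, alpha = 1, seed = 25)
  fit <- lowbmm(sim$rankings, n_star = 4, alpha = 1, iterations = 2000, seed = 26)
  expect_true(all(apply(fit$rho_samples, 1, is_permutation)))
  expect_true(all(apply(fit$aset_samples, 1, function(a) !anyDuplicated(a))))
  expect_true(all(fit$aset_samples >= 1 & fit$aset_samples <= 10))
  expect_gt(fit$accept_rho, 0)
  expect_lt(fit$accept_rho, 1)
  expect_gt(fit$accept_set, 0)
  expect_lt(fit$accept_set, 1)
  expect_identical(nrow(fit$rho_samples), 1800L)
  # seed determinism
  fit2 <- lowbmm(sim$rankings, n_star = 4, alpha = 1, iterations = 2000, seed = 26)
  expect_identical(fit$rho_samples, fit2$rho_samples)
  expect_identical(fit$aset_samples, fit2$aset_samples)
  expect_error(lowbmm(sim$rankings, n_star = 11, alpha = 3), "exceeds")
  bad <- sim$rankings; bad[2, 1] <- bad[2, 2]
  expect_error(lowbmm(bad, n_star = 4, alpha = 3), "row 2")
})

test_that("with n_star = n the sampler reduces to the fixed-scale Mallows model", {
  set.seed(27)
  rho0 <- sample.int(8)
  data <- sample_mallows(30, rho0, alpha = 10)
  fit <- lowbmm(data, n_star = 8, alpha = 10, iterations = 4000, seed = 28)
  expect_true(all(is.na(fit$accept_set)))
  # every sample keeps the full item set
  expect_true(all(apply(fit$aset_samples, 1, function(a) setequal(a, 1:8))))
  s <- posterior_summary(fit, k = 8)
  # strongly concentrated data: the posterior mode recovers the consensus;
  # align the estimate with the item order
  est <- s$rho_hat[match(1:8, s$a_hat)]
  expect_identical(as.integer(est), as.integer(rho0))
})

test_that("multiple chains are merged after per-chain burn-in", {
  sim <- simulate_toprank(n = 10, n_star = 4, N = 12, alpha = 3, seed = 29)
  fit <- lowbmm(sim$rankings, n_star = 4, alpha = 3, iterations = 1000,
                chains = 2, seed = 30)
  expect_identical(nrow(fit$rho_samples), 1800L)
  expect_identical(as.vector(table(fit$chain)), c(900L, 900L))
  expect_length(fit$accept_rho, 2L)
})
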