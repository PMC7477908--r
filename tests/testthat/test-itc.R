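test_that("representation RMSE normalises by the root entry count", {
  prob <- make_synthetic_dl_problem(8, 12, 50, 2, 0, seed = 51)
  expect_equal(representation_rmse(prob$signals, prob$dictionary, prob$codes), 0)
  # unit error everywhere -> RMSE exactly 1
  Y <- prob$dictionary %*% prob$codes + 1
  expect_equal(representation_rmse(Y, prob$dictionary, prob$codes), 1,
               tolerance = 1e-12)
  # element-wise summation oracle
  set.seed(52)
  Xr <- matrix(rnorm(12 * 50), 12)
  direct <- sqrt(sum((prob$signals - prob$dictionary %*% Xr)^2) / (8 * 50))
  expect_equal(representation_rmse(prob$signals, prob$dictionary, Xr), direct,
               tolerance = 1e-12)
})

test_that("model complexity counts nonzeros plus free dictionary entries", {
  expect_identical(model_complexity(5, 100, 36, 64), 500 + 35 * 64)
  expect_identical(model_complexity(0, 7, 4, 3), (4 - 1) * 3)
  expect_identical(model_complexity(2, 10, 1, 5), 20)
  expect_error(model_complexity(-1, 1, 1, 1), "nonnegative")
})

test_that("EBIC matches an independently composed evaluation", {
  # closed-form identities
  expect_equal(ebic(1, 3600, 2740, 100, 5, 5),
               log(3600) / 3600 * 2740, tolerance = 1e-12)
  expect_equal(ebic(0.1, 3600, 2740, 100, 5, 5),
               2 * log(0.1) + log(3600) / 3600 * 2740, tolerance = 1e-12)
  # grid against the oracle
  for (rmse in c(0.01, 0.1, 0.5, 2)) {
    for (n in c(36, 64, 128)) {
      for (s in c(1, 5)) {
        Q <- 3600; N <- 100; P <- model_complexity(s, N, 36, n)
        expect_equal(ebic(rmse, Q, P, N, n, s),
                     oracle_ebic(rmse, Q, P, N, n, s), tolerance = 1e-9)
      }
    }
  }
  expect_warning(val <- ebic(0, 100, 10, 5, 6, 2), "perfect")
  expect_identical(val, -Inf)
  expect_error(ebic(0.1, 100, 10, 5, 2, 4), "at least")
})

test_that("ERML matches the oracle and flags infeasible candidates", {
  Q <- 3600; N <- 100
  for (rmse in c(0.05, 0.1, 1)) {
    for (n in c(36, 64)) {
      P <- model_complexity(5, N, 36, n)
      dx2 <- 360
      expect_equal(erml(rmse, Q, P, N, n, 5, dx2),
                   oracle_erml(rmse, Q, P, N, n, 5, dx2), tolerance = 1e-9)
    }
  }
  # boundary algebra at Q = P + 1
  P <- 99; Qb <- 100
  v <- erml(0.2, Qb, P, 10, 5, 5, 50)
  expect_equal(v, log(0.2^2) + P * log(50 / (Qb * P)) + log(P) + 0,
               tolerance = 1e-10)
  expect_identical(erml(0.1, 100, 200, 10, 5, 5, 50), Inf)
})

test_that("atom powers are code-row norms, invariant to column order", {
  X <- rbind(c(3, 4, 0), c(0, 0, 0), c(1, 2, 2))
  expect_equal(atom_powers(X), c(5, 0, 3))
  expect_equal(atom_powers(X[, c(2, 3, 1)]), c(5, 0, 3))
})

test_that("power sorting reorders atoms without changing the product", {
  D <- make_incoherent_dictionary(6, 3, 0.8, seed = 53)
  X <- rbind(rep(1, 4), rep(3, 4), rep(2, 4))
  srt <- sort_dictionary_by_power(D, X)
  expect_equal(srt$permutation, c(2L, 3L, 1L))
  expect_lt(frob_norm(D %*% X - srt$dictionary %*% srt$codes), 1e-12)
  again <- sort_dictionary_by_power(srt$dictionary, srt$codes)
  expect_equal(again$permutation, 1:3)
})

test_that("candidate selection finds the knee of a nested representation", {
  # signals exactly generated by the top h* atoms of a sorted dictionary
  h_star <- 10
  D <- make_incoherent_dictionary(8, 16, 0.3, seed = 54)
  set.seed(55)
  X <- matrix(0, 16, 120)
  for (k in 1:120) X[sample.int(h_star, 2), k] <- rnorm(2) + 2 * sign(rnorm(1))
  Y <- D %*% X
  srt <- sort_dictionary_by_power(D, X)
  ev <- select_candidate_size(srt$dictionary, srt$codes, Y, s = 2, n_min = 8,
                              n_cand = 9)
  # brute force over every candidate using the same re-coded criterion
  expect_true(ev$n_itc %in% ev$candidate_sizes)
  expect_equal(min(ev$criterion_values),
               ev$criterion_values[match(ev$n_itc, ev$candidate_sizes)])
  expect_lte(ev$n_itc, h_star + 1)
  expect_gte(ev$n_itc, 8)

  # truncation variant on the same fixture: error identical for h >= h*,
  # so the complexity terms prefer the smallest such candidate
  evt <- select_candidate_size(srt$dictionary, srt$codes, Y, s = 2, n_min = 8,
                               n_cand = 16 - 8 + 1, recode = FALSE)
  expect_equal(evt$candidate_sizes, 8:16)
  rmse_by_hand <- sapply(8:16, function(h) {
    Dh <- srt$dictionary[, 1:h, drop = FALSE]
    Xh <- srt$codes[1:h, , drop = FALSE]
    frob_norm(Y - Dh %*% Xh) / sqrt(length(Y))
  })
  flat <- which(rmse_by_hand < rmse_by_hand[1] * 1e-6)
  expect_equal(evt$n_itc, (8:16)[flat[1]])
})

test_that("single-candidate and exhaustive grids behave as documented", {
  prob <- make_synthetic_dl_problem(8, 12, 60, 2, 0, seed = 56)
  srt <- sort_dictionary_by_power(prob$dictionary, prob$codes)
  ev1 <- select_candidate_size(srt$dictionary, srt$codes, prob$signals,
                               s = 2, n_min = 12, n_cand = 20)
  expect_equal(ev1$candidate_sizes, 12L)
  expect_equal(ev1$n_itc, 12L)
  ev2 <- select_candidate_size(srt$dictionary, srt$codes, prob$signals,
                               s = 2, n_min = 8, n_cand = 50)
  expect_equal(ev2$candidate_sizes, 8:12)
  expect_error(select_candidate_size(srt$dictionary, srt$codes, prob$signals,
                                     s = 2, n_min = 20, n_cand = 5), "n_min")
})

test_that("EBIC is monotone in complexity and in error", {
  base <- ebic(0.1, 1000, 100, 50, 20, 3)
  expect_gt(ebic(0.1, 1000, 200, 50, 20, 3), base)
  expect_gt(ebic(0.2, 1000, 100, 50, 20, 3), base)
})
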