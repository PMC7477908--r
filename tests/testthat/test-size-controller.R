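test_that("the three-rule size update follows the gap to the ITC size", {
  st <- size_controller(100, 36, e_minus = 5, e_plus = 5, gap_threshold = 5)
  expect_equal(adapt_size(st, 80), list(new_n = 95L, action = "shrink_big"))
  expect_equal(adapt_size(st, 98), list(new_n = 99L, action = "shrink_one"))
  expect_equal(adapt_size(st, 100), list(new_n = 105L, action = "grow"))
  expect_error(adapt_size(st, 101), "exceed")
  # shrinks clamp at the lower bound
  low <- size_controller(37, 36)
  expect_equal(adapt_size(low, 36)$new_n, 36L)
  clamp <- size_controller(44, 40, e_minus = 5, gap_threshold = 2)
  expect_equal(adapt_size(clamp, 41),
               list(new_n = 40L, action = "shrink_big"))
})

test_that("resizing truncates sorted atoms or spawns unit-norm random ones", {
  prob <- make_synthetic_dl_problem(8, 12, 60, 2, 0, seed = 61)
  srt <- sort_dictionary_by_power(prob$dictionary, prob$codes)
  # removing only zero-power atoms leaves the product unchanged
  X0 <- srt$codes; X0[11:12, ] <- 0
  shrunk <- resize_dictionary(srt$dictionary, X0, 10, 8)
  expect_lt(frob_norm(srt$dictionary %*% X0 -
                      shrunk$dictionary %*% shrunk$codes), 1e-12)
  # truncated-product oracle for the RMSE after a shrink
  sh <- resize_dictionary(srt$dictionary, srt$codes, 9, 8)
  expect_equal(representation_rmse(prob$signals, sh$dictionary, sh$codes),
               frob_norm(prob$signals - srt$dictionary[, 1:9] %*%
                           srt$codes[1:9, ]) / sqrt(8 * 60),
               tolerance = 1e-12)
  # growth appends unit atoms with zero code rows, reproducibly
  gr <- resize_dictionary(srt$dictionary, srt$codes, 17, 8, seed = 7)
  expect_equal(ncol(gr$dictionary), 17)
  expect_true(all(gr$codes[13:17, ] == 0))
  expect_lt(max(abs(sqrt(colSums(abs(gr$dictionary[, 13:17])^2)) - 1)), 1e-9)
  gr2 <- resize_dictionary(srt$dictionary, srt$codes, 17, 8, seed = 7)
  expect_identical(gr$dictionary, gr2$dictionary)
  expect_error(resize_dictionary(srt$dictionary, srt$codes, 5, 8), "n_min")
})

test_that("the controller freezes at the last ITC size after the search phase", {
  st <- size_controller(50, 20, search_iters = 3, refine_iters = 2)
  st$n_itc_last <- 30L
  st <- step_and_maybe_freeze(st)
  st <- step_and_maybe_freeze(st)
  expect_false(st$frozen)
  st <- step_and_maybe_freeze(st)
  expect_true(st$frozen)
  expect_equal(st$n_current, 30L)
  # frozen state never changes size again
  st$n_itc_last <- 45L
  st <- step_and_maybe_freeze(st)
  expect_equal(st$n_current, 30L)
  expect_error(adapt_size(st, 25), "frozen")
  # immediate freeze with a zero-length search phase
  st0 <- size_controller(50, 20, search_iters = 0)
  st0$n_itc_last <- 22L
  st0 <- step_and_maybe_freeze(st0)
  expect_true(st0$frozen)
  expect_equal(st0$n_current, 22L)
})

test_that("adaptive learning recovers a planted dictionary size", {
  hits <- 0L
  for (sd in 1:3) {
    prob <- make_synthetic_dl_problem(36, 48, 500, 5, 0, seed = sd)
    fit <- learn_adaptive_dictionary(prob$signals, T0 = 5, s = 5,
                                     n_init = 80, n_min = 36,
                                     search_iters = 15, refine_iters = 3,
                                     seed = sd)
    expect_gte(ncol(fit$dictionary), 36)
    expect_true(fit$state$frozen)
    expect_equal(ncol(fit$dictionary), fit$state$n_current)
    if (abs(fit$state$n_current - 48) <= 5) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("size trajectories are reproducible and respect the floor", {
  prob <- make_synthetic_dl_problem(16, 24, 200, 3, 0, seed = 62)
  a <- learn_adaptive_dictionary(prob$signals, T0 = 3, s = 3, n_init = 30,
                                 n_min = 16, search_iters = 6,
                                 refine_iters = 2, seed = 9)
  b <- learn_adaptive_dictionary(prob$signals, T0 = 3, s = 3, n_init = 30,
                                 n_min = 16, search_iters = 6,
                                 refine_iters = 2, seed = 9)
  expect_identical(a$trajectory, b$trajectory)
  expect_true(all(a$trajectory$n >= 16))
  frozen_n <- a$trajectory$n[a$trajectory$action == "frozen"]
  expect_true(length(unique(frozen_n)) <= 1)
})
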