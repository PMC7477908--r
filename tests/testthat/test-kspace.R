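test_that("centred unitary FFT puts a constant's energy in the DC bin", {
  S <- fft2c(matrix(3, 8, 8))
  expect_equal(S[5, 5], 3 * 8 + 0i, tolerance = 1e-12)
  off <- S; off[5, 5] <- 0
  expect_lt(max(abs(off)), 1e-12)
})

test_that("fft2c/ifft2c round-trip and Parseval hold to machine precision", {
  x <- seeded_complex_matrix(32, seed = 1)
  expect_lt(max(abs(ifft2c(fft2c(x)) - x)), 1e-10)
  y <- seeded_complex_matrix(16, seed = 2)
  expect_lt(abs(frob_norm(y) - frob_norm(fft2c(y))), 1e-10)
  # odd sizes round-trip too (shift conventions must be inverses)
  z <- seeded_complex_matrix(15, 9, seed = 3)
  expect_lt(max(abs(ifft2c(fft2c(z)) - z)), 1e-10)
  expect_error(fft2c(array(1, c(2, 2, 2))), "2D")
})

test_that("sampling masks hit the requested fraction and kinds", {
  expect_true(all(make_sampling_mask(16, 16, 1, "uniform_random", 1)$grid))

  vd <- make_sampling_mask(128, 128, 4, "variable_density_2d", seed = 3)
  frac <- mean(vd$grid)
  expect_gte(frac, 0.20)
  expect_lte(frac, 0.30)
  ur <- make_sampling_mask(128, 128, 4, "uniform_random", seed = 3)
  centre_dist <- function(g) {
    idx <- which(g, arr.ind = TRUE)
    mean(sqrt((idx[, 1] - 65)^2 + (idx[, 2] - 65)^2))
  }
  expect_lt(centre_dist(vd$grid), centre_dist(ur$grid))

  cl <- make_sampling_mask(128, 128, 10, "cartesian_lines", seed = 4)
  full_rows <- sum(rowSums(cl$grid) == 128)
  expect_true(full_rows %in% c(12L, 13L))
  expect_true(all(rowSums(cl$grid) %in% c(0L, 128L)))

  # DC always sampled; masks deterministic per seed
  expect_true(vd$grid[65, 65])
  expect_identical(vd$grid,
                   make_sampling_mask(128, 128, 4, "variable_density_2d",
                                      seed = 3)$grid)
  expect_error(make_sampling_mask(16, 16, 0.5, "full"), ">= 1")
})

test_that("undersampling zeroes the complement and shrinks energy", {
  img <- generate_phantom(phantom_spec(64))
  full <- undersample(img, make_sampling_mask(64, 64, 1, "full"))
  expect_lt(max(abs(full$values - fft2c(img))), 1e-12)

  mask <- make_sampling_mask(64, 64, 4, "variable_density_2d", seed = 5)
  y <- undersample(img, mask)
  expect_true(all(y$values[!mask$grid] == 0))
  expect_lte(frob_norm(y$values), frob_norm(fft2c(img)))
  expect_error(undersample(img, make_sampling_mask(32, 32, 2)), "shapes")
})

test_that("zero-filled reconstruction recovers fully sampled data", {
  img <- generate_phantom(phantom_spec(64))
  y <- undersample(img, make_sampling_mask(64, 64, 1, "full"))
  expect_lt(max(abs(zero_filled_recon(y) - img)), 1e-10)

  none <- structure(list(values = matrix(0 + 0i, 64, 64),
                         mask = matrix(FALSE, 64, 64),
                         is_measurement = TRUE), class = "kspace_grid")
  expect_true(all(zero_filled_recon(none) == 0))

  y4 <- undersample(img, make_sampling_mask(64, 64, 4, "variable_density_2d",
                                            seed = 1))
  expect_lt(psnr(img, zero_filled_recon(y4)), psnr(img, zero_filled_recon(y)))
})

test_that("k-space data update matches the closed form", {
  mask <- matrix(FALSE, 2, 2); mask[1, 1] <- TRUE
  M <- matrix(2 + 0i, 2, 2); M0 <- matrix(8 + 0i, 2, 2)
  out <- kspace_data_update(M, M0, mask, 3)
  expect_equal(out[1, 1], 6.5 + 0i)           # (2 + 3*8)/(1+3)
  expect_equal(out[2, 2], 2 + 0i)             # untouched off the mask

  Mr <- seeded_complex_matrix(16, seed = 6)
  M0r <- seeded_complex_matrix(16, seed = 7)
  g <- matrix(Re(seeded_complex_matrix(16, seed = 8)) > 0, 16, 16)
  expect_identical(kspace_data_update(Mr, M0r, g, 0), Mr)
  big <- kspace_data_update(Mr, M0r, g, 1e6)
  expect_lt(max(abs(big[g] - M0r[g])), 1e-5 * max(abs(M0r)))
  expect_identical(big[!g], Mr[!g])
  expect_error(kspace_data_update(Mr, M0r, g, -1), "nonnegative")
})

test_that("the update is a convex combination on the sampled set", {
  M <- seeded_complex_matrix(8, seed = 9)
  M0 <- seeded_complex_matrix(8, seed = 10)
  g <- matrix(rep(c(TRUE, FALSE), 32), 8, 8)
  for (v in c(0.1, 1, 7)) {
    out <- kspace_data_update(M, M0, g, v)
    lam <- v / (1 + v)
    expect_lt(max(abs(out[g] - ((1 - lam) * M[g] + lam * M0[g]))), 1e-12)
  }
  # idempotent when the model already matches the measurements on the mask
  Magree <- M; Magree[g] <- M0[g]
  expect_lt(max(abs(kspace_data_update(Magree, M0, g, 3) - Magree)), 1e-12)
})
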