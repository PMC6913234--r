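test_that("the default grid factorisation yields 7650 candidates", {
  spec <- grid_spec()
  expect_equal(spec$n_angles * spec$n_ecc * spec$n_sigma, 7650)
})

test_that("a singleton grid reproduces predict_timeseries", {
  m <- tiny_movie()
  hrf <- hrf_spec()
  spec <- grid_spec(n_angles = 1, n_ecc = 1, ecc_range = c(3, 3),
                    n_sigma = 1, sigma_range = c(1, 1))
  g <- build_grid(spec, m, hrf)
  expect_equal(nrow(g$candidates), 1)
  direct <- predict_timeseries(prf_params(3, 0, 1), m, hrf)
  expect_equal(g$predictions[, 1], as.numeric(direct), tolerance = 1e-10)
})

test_that("grid flags non-overlapping candidates as degenerate", {
  m <- tiny_movie()
  spec <- grid_spec(n_angles = 4, n_ecc = 3, ecc_range = c(5, 40),
                    n_sigma = 2, sigma_range = c(0.3, 0.5))
  g <- build_grid(spec, m, hrf_spec())
  far <- g$candidates$ecc > 9.5 + 2 * g$candidates$sigma
  expect_true(all(g$degenerate[far]))
  expect_true(all(g$predictions[, g$degenerate] == 0))
})

test_that("grid build is deterministic", {
  m <- tiny_movie()
  spec <- small_grid_spec()
  g1 <- build_grid(spec, m, hrf_spec(), chunk_size = 100L)
  g2 <- build_grid(spec, m, hrf_spec(), chunk_size = 997L)
  expect_identical(g1$candidates, g2$candidates)
  expect_equal(g1$predictions, g2$predictions, tolerance = 1e-12)
})

test_that("coarse fit recovers a grid candidate from its own prediction", {
  g <- fit_grid()
  idx <- 123
  obs <- g$predictions[, idx]
  cf <- coarse_fit(obs, g)
  expect_equal(cf$index, idx)
  expect_equal(cf$r_squared, 1, tolerance = 1e-9)
  expect_true(cf$passed_gate)
})

test_that("coarse fit equals an exhaustive correlation loop", {
  m <- fit_movie()
  g <- fit_grid()
  set.seed(11)
  truth <- prf_params(1.9, -3.2, 1.1)
  obs <- as.numeric(predict_timeseries(truth, m)) + rnorm(250, 0, 1.5)
  cf <- coarse_fit(obs, g)
  r_loop <- rep(-Inf, nrow(g$candidates))
  for (i in seq_len(nrow(g$candidates))) {
    if (!g$degenerate[i]) r_loop[i] <- cor(obs, g$predictions[, i])
  }
  expect_equal(cf$index, which.max(r_loop))
  expect_equal(cf$r_squared, max(r_loop)^2, tolerance = 1e-12)
})

test_that("coarse fit marks degenerate observations as failed", {
  g <- fit_grid()
  cf <- coarse_fit(rep(2, nrow(g$predictions)), g)
  expect_true(cf$failed)
})

test_that("white-noise gate passage matches a permutation null", {
  # the gate is permissive: the max grid correlation of pure noise almost
  # always exceeds r^2 = 0.01, and a permutation null behaves identically
  g <- fit_grid()
  set.seed(12)
  n <- nrow(g$predictions)
  pass_noise <- replicate(40, coarse_fit(rnorm(n), g)$passed_gate)
  base <- as.numeric(predict_timeseries(prf_params(2, 2, 1), fit_movie()))
  pass_perm <- replicate(40, coarse_fit(sample(base), g)$passed_gate)
  expect_lt(abs(mean(pass_noise) - mean(pass_perm)), 0.2)
})

test_that("fine fit is a fixed point at the noiseless truth", {
  m <- fit_movie()
  truth <- prf_params(1.23, -2.41, 0.87)
  obs <- as.numeric(predict_timeseries(truth, m))
  ff <- fine_fit(obs, truth, m)
  expect_lt(abs(ff$params$x0 - truth$x0), 1e-3)
  expect_lt(abs(ff$params$y0 - truth$y0), 1e-3)
  expect_lt(abs(ff$params$sigma - truth$sigma), 1e-3)
  expect_gt(ff$r_squared, 1 - 1e-9)
})

test_that("fine fit recovers an off-grid truth from the coarse start", {
  m <- fit_movie()
  g <- fit_grid()
  truth <- prf_params(1.23, -2.41, 0.87)
  obs <- as.numeric(predict_timeseries(truth, m))
  cf <- coarse_fit(obs, g)
  ff <- fine_fit(obs, cf$params, m)
  expect_lt(abs(ff$params$x0 - truth$x0), 0.05)
  expect_lt(abs(ff$params$y0 - truth$y0), 0.05)
  expect_lt(abs(ff$params$sigma - truth$sigma), 0.05)
  expect_gte(ff$r_squared, cf$r_squared - 1e-12)
})

test_that("affine transforms of the data leave pRF estimates unchanged", {
  m <- fit_movie()
  g <- fit_grid()
  set.seed(13)
  obs <- as.numeric(predict_timeseries(prf_params(2.5, 1.5, 1.2), m)) +
    rnorm(250, 0, 1.2)
  cf1 <- coarse_fit(obs, g)
  ff1 <- fine_fit(obs, cf1$params, m)
  obs2 <- 3.7 * obs - 2
  cf2 <- coarse_fit(obs2, g)
  ff2 <- fine_fit(obs2, cf2$params, m)
  expect_equal(cf1$index, cf2$index)
  expect_lt(abs(ff1$params$x0 - ff2$params$x0), 1e-6)
  expect_lt(abs(ff1$params$y0 - ff2$params$y0), 1e-6)
  expect_lt(abs(ff1$params$sigma - ff2$params$sigma), 1e-6)
  expect_lt(abs(ff1$r_squared - ff2$r_squared), 1e-6)
})

test_that("fit_betas matches the closed-form normal equations", {
  set.seed(14)
  pred <- as.numeric(scale(rnorm(100)))
  # exact line
  expect_equal(fit_betas(2 * pred + 3, pred), c(beta1 = 2, beta0 = 3),
               tolerance = 1e-10)
  # orthogonal observation: beta1 = 0
  orth <- residuals(lm(rnorm(100) ~ pred))
  expect_lt(abs(fit_betas(orth, pred)[["beta1"]]), 1e-10)
  # random observation vs lm()
  y <- rnorm(100)
  bl <- coef(lm(y ~ pred))
  b <- fit_betas(y, pred)
  expect_equal(unname(b[["beta1"]]), unname(bl[2]), tolerance = 1e-10)
  expect_equal(unname(b[["beta0"]]), unname(bl[1]), tolerance = 1e-10)
})

test_that("fit_map recovers noiseless vertices with near-perfect fits", {
  m <- fit_movie()
  g <- fit_grid()
  hrf <- hrf_spec()
  truth <- make_truth_layout(10, ecc_range = c(1, 6), seed = 15)
  runs <- simulate_runs(truth, m, hrf, n_runs = 1, noise_sd = 0,
                        drift = drift_spec(linear_slope = 0), seed = 16)
  avg <- suppressWarnings(average_runs(preprocess_runs(runs)))
  fits <- fit_map(avg, g, m, hrf)
  expect_equal(nrow(fits), 10)
  expect_true(all(fits$stage == "fine"))
  expect_true(all(fits$r2 > 0.97))
  expect_lt(median(abs(fits$sigma - truth$sigma) / truth$sigma), 0.05)
})

test_that("pure-noise vertices pass the permissive gate but not the summary threshold", {
  m <- fit_movie()
  g <- fit_grid()
  set.seed(17)
  noise <- matrix(rnorm(250 * 10), 250, 10)
  fits <- fit_map(noise, g, m, hrf_spec())
  expect_equal(nrow(fits), 10)
  # the coarse gate at 0.01 rejects almost nothing (max over thousands of
  # candidates), but none of the noise fits clears the 0.15 inclusion bar
  expect_true(all(fits$r2[fits$stage != "failed"] < 0.15))
})

test_that("fit_map is deterministic and complete", {
  m <- fit_movie()
  g <- fit_grid()
  set.seed(18)
  data <- matrix(rnorm(250 * 4), 250, 4)
  data[, 2] <- as.numeric(predict_timeseries(prf_params(2, 2, 1), m)) * 2 +
    data[, 2] * 0.3
  f1 <- fit_map(data, g, m, hrf_spec())
  f2 <- fit_map(data, g, m, hrf_spec())
  expect_identical(f1, f2)
  expect_equal(f1$vertex_id, 1:4)
})

test_that("fit tables round-trip through TSV", {
  fits <- data.frame(vertex_id = 1:3, x0 = c(1, 2, NA), y0 = c(0, -1, NA),
                     sigma = c(1, 2, NA), beta1 = c(1.5, 2, NA),
                     beta0 = c(0, 1, NA), r2 = c(0.5, 0.9, NA),
                     stage = c("fine", "fine", "failed"))
  path <- tempfile(fileext = ".tsv")
  write_fits_tsv(fits, path)
  expect_equal(read_fits_tsv(path), fits)
})
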