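test_that("shoelace area matches known polygons and the fan oracle", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(neighbor_polygon_area(square), 1)
  collinear <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_equal(neighbor_polygon_area(collinear), 0)
  expect_true(is.na(neighbor_polygon_area(rbind(c(0, 0), c(1, 1)))))
  set.seed(41)
  for (rep in 1:5) {
    ang <- sort(runif(6, 0, 2 * pi))
    hexagon <- cbind(cos(ang), sin(ang)) * runif(6, 0.5, 2)
    expect_equal(neighbor_polygon_area(hexagon), bf_fan_area(hexagon),
                 tolerance = 1e-12)
  }
})

test_that("constant-magnification mesh gives constant CMF", {
  mesh <- make_flat_mesh(10, list(type = "constant", M = 2))
  cmf <- cmf_map(mesh)
  interior <- !is.na(cmf)
  expect_gt(sum(interior), 50)
  expect_true(all(abs(cmf[interior] - 2) < 1e-9))
})

test_that("CMF is homogeneous of degree one in cortical coordinates", {
  mesh <- make_flat_mesh(8, list(type = "constant", M = 1.5))
  base <- cmf_map(mesh)
  scaled <- mesh
  scaled$vertex_positions <- mesh$vertex_positions * 3
  expect_equal(cmf_map(scaled), 3 * base, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("log-polar mesh CMF follows the analytic magnification", {
  mesh <- make_flat_mesh(16, list(type = "logpolar", k = 15, a = 0.75,
                                  ecc_range = c(1, 8), v_extent_mm = 2))
  cmf <- cmf_map(mesh)
  truth <- mesh$fits$true_cmf
  interior <- !is.na(cmf)
  rel <- abs(cmf[interior] - truth[interior]) / truth[interior]
  expect_lt(max(rel), 0.05)
  # magnification decreases with eccentricity
  ord <- order(mesh$fits$ecc[interior])
  expect_lt(cor(mesh$fits$ecc[interior], cmf[interior]), -0.9)
})

test_that("degenerate visual polygons yield NA CMF", {
  mesh <- make_flat_mesh(6, list(type = "constant", M = 2))
  mesh$fits$x0[] <- 1   # all pRF centres identical: zero visual area
  mesh$fits$y0[] <- 1
  expect_true(all(is.na(cmf_map(mesh))))
})

test_that("map smoothing preserves constants and approaches identity", {
  mesh <- make_flat_mesh(8, list(type = "constant", M = 2))
  n <- nrow(mesh$vertex_positions)
  const <- rep(3.3, n)
  expect_equal(smooth_map(mesh, const, 3), const, tolerance = 1e-12)
  set.seed(42)
  vals <- rnorm(n)
  expect_equal(smooth_map(mesh, vals, 1e-6), vals, tolerance = 1e-9)
})

test_that("impulse smoothing matches a direct weight-matrix computation", {
  mesh <- make_flat_mesh(7, list(type = "constant", M = 2))
  n <- nrow(mesh$vertex_positions)
  vals <- numeric(n); vals[25] <- 1
  fwhm <- 3
  out <- smooth_map(mesh, vals, fwhm)
  sd_mm <- fwhm / (2 * sqrt(2 * log(2)))
  pos <- mesh$vertex_positions
  w <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    d2 <- sum((pos[i, ] - pos[j, ])^2)
    if (d2 <= (3 * sd_mm)^2) w[i, j] <- exp(-d2 / (2 * sd_mm^2))
  }
  w <- w / rowSums(w)
  expect_equal(out, as.vector(w %*% vals), tolerance = 1e-9)
  expect_gt(sum(out > 0), 1)   # mass spreads beyond the impulse vertex
})

test_that("NA values are excluded and weights renormalised in smoothing", {
  mesh <- make_flat_mesh(6, list(type = "constant", M = 2))
  n <- nrow(mesh$vertex_positions)
  vals <- rep(2, n)
  vals[c(3, 17)] <- NA
  out <- smooth_map(mesh, vals, 4)
  expect_equal(out, rep(2, n), tolerance = 1e-12)
})

test_that("bin_summarize computes binned statistics with exclusions", {
  ecc <- c(1, 1.2, 1.4, 2.5, 2.6, 9.5)
  vals <- c(1, 2, 3, 10, 20, 7)
  out <- bin_summarize(ecc, vals, stat = "mean", n_boot = 200)
  expect_equal(out$value[1], 2)            # mean of {1,2,3} in [0.5,1.5)
  expect_equal(out$value[3], 15)           # [2.5,3.5)
  expect_equal(out$value[9], 7)            # final bin closed at 9.5
  expect_equal(out$n, c(3L, 0L, 2L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_true(out$empty[2])
  # r2 threshold excludes vertices at or below 0.15
  out2 <- bin_summarize(ecc, vals, stat = "mean",
                        r_squared = c(0.10, 0.2, 0.2, 0.2, 0.15, 0.2),
                        r2_threshold = 0.15, n_boot = 200)
  expect_equal(out2$value[1], 2.5)         # vertex with r2 = 0.10 excluded
  expect_equal(out2$n[3], 1L)              # r2 = 0.15 not strictly above
})

test_that("constant bins give zero-width confidence intervals", {
  out <- bin_summarize(rep(1, 20), rep(5, 20), stat = "median", n_boot = 200)
  expect_equal(out$ci_low[1], 5)
  expect_equal(out$ci_high[1], 5)
  expect_true(all(out$ci_low <= out$value, na.rm = TRUE))
  expect_true(all(out$ci_high >= out$value, na.rm = TRUE))
})

test_that("bootstrap intervals are approximately calibrated", {
  # reduced-size calibration run; the acceptance suite uses 2000 replicates
  set.seed(43)
  hits <- replicate(400, {
    x <- rnorm(50)
    ci <- prfmap:::boot_ci(x, mean, n_boot = 500)
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("circular correlation is 1 for identical and rotated maps", {
  set.seed(44)
  a <- runif(50, -pi, pi)
  expect_equal(circular_corr(a, a), 1, tolerance = 1e-12)
  expect_equal(circular_corr(a, a + 1.3), 1, tolerance = 1e-12)
  expect_true(is.na(circular_corr(a[1:2], a[1:2])))
  expect_true(is.na(circular_corr(rep(0.5, 10), a[1:10])))
})

test_that("independent angles have near-zero circular correlation", {
  set.seed(45)
  a <- runif(1000, 0, 2 * pi)
  b <- runif(1000, 0, 2 * pi)
  expect_lt(abs(circular_corr(a, b)), 0.07)
})

test_that("compare_maps restricts to vertices above threshold in both maps", {
  set.seed(46)
  n <- 200
  theta <- runif(n, 0, 2 * pi)
  ecc <- sqrt(runif(n, 0.25, 64))
  fa <- data.frame(vertex_id = 1:n, x0 = ecc * cos(theta),
                   y0 = ecc * sin(theta), r2 = runif(n, 0.2, 0.9))
  fb <- fa
  cmp <- compare_maps(fa, fb)
  expect_equal(cmp$polar_r, 1, tolerance = 1e-12)
  expect_equal(cmp$ecc_rho, 1, tolerance = 1e-12)
  expect_equal(cmp$n_common, n)
  # vertices below threshold in either map are excluded
  fb2 <- fb
  fb2$r2[1:50] <- 0.05
  expect_equal(compare_maps(fa, fb2)$n_common, n - 50)
  # symmetry
  cmp_ab <- compare_maps(fa, fb2)
  cmp_ba <- compare_maps(fb2, fa)
  expect_equal(cmp_ab$polar_r, cmp_ba$polar_r, tolerance = 1e-12)
  expect_equal(cmp_ab$ecc_rho, cmp_ba$ecc_rho, tolerance = 1e-12)
})

test_that("shuffled maps decorrelate", {
  set.seed(47)
  n <- 1000
  theta <- runif(n, 0, 2 * pi)
  ecc <- sqrt(runif(n, 0.25, 64))
  fa <- data.frame(vertex_id = 1:n, x0 = ecc * cos(theta),
                   y0 = ecc * sin(theta), r2 = runif(n, 0.2, 0.9))
  perm <- sample(n)
  fb <- data.frame(vertex_id = 1:n, x0 = fa$x0[perm], y0 = fa$y0[perm],
                   r2 = fa$r2[perm])
  cmp <- compare_maps(fa, fb)
  expect_lt(abs(cmp$polar_r), 0.07)
  expect_lt(abs(cmp$ecc_rho), 0.07)
})
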