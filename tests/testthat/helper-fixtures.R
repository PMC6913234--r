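# Shared fixtures and independent brute-force oracles.
# Expensive objects are built once per test run and cached in this env.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A light design: 20 x 20 mask, full default schedule (250 frames w/o dummies).
tiny_design <- function(...) {
  bar_design(mask_resolution_px = 20, ...)
}

tiny_movie <- function() {
  fixture("tiny_movie", function() {
    generate_apertures(tiny_design(), include_dummies = FALSE)
  })
}

# Mid-size fixtures for fitting tests: 50 x 50 mask, small search grid.
fit_movie <- function() {
  fixture("fit_movie", function() {
    generate_apertures(bar_design(mask_resolution_px = 50),
                       include_dummies = FALSE)
  })
}

small_grid_spec <- function() {
  grid_spec(n_angles = 10, n_ecc = 8, ecc_range = c(0.5, 8),
            n_sigma = 6, sigma_range = c(0.3, 4))
}

fit_grid <- function() {
  fixture("fit_grid", function() {
    build_grid(small_grid_spec(), fit_movie(), hrf_spec())
  })
}

# ---- independent oracles (explicit loops, no vectorisation) ----

# Per-pixel point-in-bar classification for one bar frame.
bf_bar_mask <- function(step_index, orientation_deg, design) {
  n_px <- design$mask_resolution_px
  dpp <- design$aperture_diameter_deg / n_px
  half <- design$aperture_diameter_deg / 2
  step <- bar_step_deg(design)
  pos <- (step_index - (design$steps_per_sweep + 1) / 2) * step
  phi <- orientation_deg * pi / 180
  out <- matrix(0, n_px, n_px)
  for (i in seq_len(n_px)) {
    for (j in seq_len(n_px)) {
      x <- (i - 0.5) * dpp - half
      y <- (j - 0.5) * dpp - half
      r <- sqrt(x^2 + y^2)
      in_bar <- abs(x * sin(phi) + y * cos(phi) - pos) <=
        design$bar_width_deg / 2
      if (in_bar && r <= half && r >= design$hole_radius_deg) out[i, j] <- 1
    }
  }
  out
}

# Naive double-loop neural response.
bf_neural_response <- function(profile, movie) {
  nf <- n_frames(movie)
  out <- numeric(nf)
  for (t in seq_len(nf)) {
    acc <- 0
    for (i in seq_len(movie$n_px)) {
      for (j in seq_len(movie$n_px)) {
        acc <- acc + movie$frames[i, j, t] * profile[i, j]
      }
    }
    out[t] <- acc
  }
  out
}

# Naive causal convolution truncated to length(x).
bf_convolve <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_along(k)) {
      if (i - j + 1 >= 1) out[i] <- out[i] + x[i - j + 1] * k[j]
    }
  }
  out
}

# Triangle-fan polygon area (oracle for the shoelace formula).
bf_fan_area <- function(points) {
  p0 <- points[1, ]
  total <- 0
  for (i in 2:(nrow(points) - 1)) {
    a <- points[i, ] - p0
    b <- points[i + 1, ] - p0
    total <- total + (a[1] * b[2] - a[2] * b[1]) / 2
  }
  abs(total)
}
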