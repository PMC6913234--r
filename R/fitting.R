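# Two-stage pRF fitting: coarse grid correlation, simplex refinement, betas.

#' Search-grid specification for the coarse fit
#'
#' The coarse fit correlates each observed series against predictions for a
#' Cartesian product of polar angle x eccentricity x pRF size. The default
#' factorisation (30 angles x 17 log-spaced eccentricities x 15 log-spaced
#' sigmas) yields 7650 candidates.
#'
#' @param n_angles Number of equally spaced polar angles.
#' @param n_ecc Number of eccentricities.
#' @param ecc_range Eccentricity range in degrees (log-spaced).
#' @param n_sigma Number of pRF sizes.
#' @param sigma_range Sigma range in degrees (log-spaced).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_angles = 30, n_ecc = 17, ecc_range = c(0.25, 9.5),
                      n_sigma = 15, sigma_range = c(0.1, 5)) {
  stopifnot(n_angles >= 1, n_ecc >= 1, n_sigma >= 1,
            all(ecc_range > 0), all(sigma_range > 0),
            ecc_range[2] >= ecc_range[1], sigma_range[2] >= sigma_range[1])
  structure(list(n_angles = n_angles, n_ecc = n_ecc, ecc_range = ecc_range,
                 n_sigma = n_sigma, sigma_range = sigma_range),
            class = "grid_spec")
}

log_spaced <- function(n, range) {
  if (n == 1) return(range[1])
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Build the coarse-fit search grid
#'
#' Converts the polar-angle x eccentricity x sigma product into Cartesian
#' pRF candidates and precomputes each candidate's z-scored predicted time
#' series. Candidates whose prediction has zero variance (no stimulus
#' overlap) are flagged degenerate and skipped by [coarse_fit()].
#'
#' @param spec A [grid_spec()].
#' @param movie An `aperture_movie` without dummy frames.
#' @param hrf An [hrf_spec()].
#' @param chunk_size Candidates per block in the vectorised build (memory
#'   control only; no effect on results).
#' @return An object of class `search_grid`: `candidates` (data frame with
#'   `x0`, `y0`, `sigma`, `angle_deg`, `ecc`), `predictions` (frames x
#'   candidates matrix, z-scored columns; zeros for degenerate candidates),
#'   `degenerate` (logical), and the `spec`.
#' @export
build_grid <- function(spec = grid_spec(), movie, hrf = hrf_spec(),
                       chunk_size = 500L) {
  stopifnot(inherits(spec, "grid_spec"), inherits(movie, "aperture_movie"))
  angles <- seq(0, 360, length.out = spec$n_angles + 1)[seq_len(spec$n_angles)]
  eccs <- log_spaced(spec$n_ecc, spec$ecc_range)
  sigmas <- log_spaced(spec$n_sigma, spec$sigma_range)
  cand <- expand.grid(angle_deg = angles, ecc = eccs, sigma = sigmas,
                      KEEP.OUT.ATTRS = FALSE)
  cand$x0 <- cand$ecc * cos(cand$angle_deg * pi / 180)
  cand$y0 <- cand$ecc * sin(cand$angle_deg * pi / 180)
  ctx <- model_context(movie, hrf)
  n_cand <- nrow(cand)
  nf <- ctx$n_frames
  preds <- matrix(0, nf, n_cand)
  for (start in seq(1L, n_cand, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n_cand)
    # pixel weights for the block: n_pixels x block
    d2 <- outer(ctx$px, cand$x0[idx], "-")^2 + outer(ctx$py, cand$y0[idx], "-")^2
    w <- exp(-sweep(d2, 2, 2 * cand$sigma[idx]^2, "/"))
    preds[, idx] <- ctx$convmat %*% (ctx$fm %*% w)
  }
  mu <- colMeans(preds)
  sdv <- sqrt(colSums(sweep(preds, 2, mu)^2) / (nf - 1))
  degenerate <- !is.finite(sdv) | sdv < 1e-12
  sdv[degenerate] <- 1
  preds <- sweep(sweep(preds, 2, mu), 2, sdv, "/")
  preds[, degenerate] <- 0
  structure(list(candidates = cand[, c("x0", "y0", "sigma", "angle_deg", "ecc")],
                 predictions = preds, degenerate = degenerate, spec = spec),
            class = "search_grid")
}

#' @export
print.search_grid <- function(x, ...) {
  cat(sprintf("search_grid: %d candidates (%d degenerate), %d frames\n",
              nrow(x$candidates), sum(x$degenerate), nrow(x$predictions)))
  invisible(x)
}

#' Coarse fit: exhaustive grid correlation
#'
#' Finds the grid candidate whose prediction has the maximal Pearson
#' correlation with the observed series. The candidate is retained for
#' refinement only when the squared correlation exceeds the gate threshold
#' (default 0.01). Ties are broken by the first candidate in grid order.
#'
#' @param observed Numeric vector (preprocessed; any affine scale).
#' @param grid A [build_grid()] result.
#' @param gate R-squared gate below which the vertex is not refined.
#' @return A list with `params` ([prf_params()]), `r_squared`, `index`
#'   (candidate row), `passed_gate`, and `failed` (TRUE when the observed
#'   series is degenerate).
#' @export
coarse_fit <- function(observed, grid, gate = 0.01) {
  stopifnot(inherits(grid, "search_grid"))
  nf <- nrow(grid$predictions)
  if (length(observed) != nf) stop("observed length does not match grid")
  oz <- zscore(observed)
  if (is_degenerate(oz)) {
    return(list(params = NULL, r_squared = NA_real_, index = NA_integer_,
                passed_gate = FALSE, failed = TRUE))
  }
  r <- as.vector(crossprod(grid$predictions, oz)) / (nf - 1)
  r[grid$degenerate] <- -Inf
  best <- which.max(r)
  cand <- grid$candidates[best, ]
  list(params = prf_params(cand$x0, cand$y0, cand$sigma),
       r_squared = r[best]^2, index = best,
       passed_gate = r[best]^2 > gate, failed = FALSE)
}

#' Fine fit: simplex refinement of pRF parameters
#'
#' Maximises the Pearson correlation between the observed series and the
#' forward-model prediction over (x0, y0, sigma) with Nelder-Mead, starting
#' from the coarse-fit candidate. Sigma is kept positive through a log
#' reparameterisation. If the optimizer fails to improve on the start, the
#' start is returned (`stage = "coarse-only"`).
#'
#' @param observed Numeric vector.
#' @param init A [prf_params()] starting point (from [coarse_fit()]).
#' @param movie An `aperture_movie` without dummies.
#' @param hrf An [hrf_spec()].
#' @param control Passed to [stats::optim()] (Nelder-Mead); defaults
#'   `maxit = 400`, `reltol = 1e-6`.
#' @param ctx Optional precomputed [model context][predict_timeseries]
#'   (internal use by [fit_map()]).
#' @return A list with `params`, `r_squared` and `stage`
#'   (`"fine"`/`"coarse-only"`).
#' @export
fine_fit <- function(observed, init, movie, hrf = hrf_spec(),
                     control = list(maxit = 400, reltol = 1e-6), ctx = NULL) {
  stopifnot(inherits(init, "prf_params"))
  if (is.null(ctx)) ctx <- model_context(movie, hrf)
  oz <- zscore(observed)
  if (is_degenerate(oz)) stop("observed series is degenerate")
  nf <- ctx$n_frames
  negcor <- function(p) {
    pred <- predict_fast(p[1], p[2], exp(p[3]), ctx)
    if (is.null(pred)) return(2)   # no overlap: worse than any correlation
    -sum(pred * oz) / (nf - 1)
  }
  p0 <- c(init$x0, init$y0, log(init$sigma))
  r0 <- -negcor(p0)
  opt <- tryCatch(
    stats::optim(p0, negcor, method = "Nelder-Mead", control = control),
    error = function(e) NULL
  )
  if (is.null(opt) || -opt$value < r0 - 1e-12) {
    return(list(params = init, r_squared = r0^2, stage = "coarse-only"))
  }
  list(params = prf_params(opt$par[1], opt$par[2], exp(opt$par[3])),
       r_squared = opt$value^2, stage = "fine")
}

#' Amplitude and baseline by ordinary least squares
#'
#' Regresses the observed series on the (z-scored) model prediction,
#' returning the amplitude `beta1` and baseline intercept `beta0`.
#'
#' @param observed_raw Observed series (original scale).
#' @param prediction Model prediction (z-scored).
#' @return Named numeric vector `c(beta1, beta0)`.
#' @export
fit_betas <- function(observed_raw, prediction) {
  if (length(observed_raw) != length(prediction)) {
    stop("observed and prediction lengths differ")
  }
  vx <- stats::var(prediction)
  if (vx < 1e-24) stop("prediction has zero variance")
  b1 <- stats::cov(observed_raw, prediction) / vx
  c(beta1 = b1, beta0 = mean(observed_raw) - b1 * mean(prediction))
}

#' Fit pRF parameters for every vertex of a data matrix
#'
#' Runs the two-stage procedure per vertex: coarse grid correlation, the
#' R-squared gate, simplex fine fit, then amplitude/baseline regression
#' against the final prediction. Deterministic given identical inputs.
#'
#' @param data Time x vertices matrix of preprocessed series; an optional
#'   `degenerate_vertices` attribute (from [preprocess_runs()] /
#'   [average_runs()]) marks vertices skipped as failed.
#' @param grid A [build_grid()] result.
#' @param movie,hrf The movie and HRF used to build the grid.
#' @param gate Coarse-fit R-squared gate (default 0.01).
#' @param fine Run the fine fit? (default TRUE).
#' @param control Fine-fit optimizer control.
#' @param verbose Print progress every 50 vertices.
#' @return Data frame with one row per vertex: `vertex_id`, `x0`, `y0`,
#'   `sigma`, `beta1`, `beta0`, `r2`, `stage` (fine / coarse-only / failed).
#'   Parameter columns are `NA` for failed vertices.
#' @export
fit_map <- function(data, grid, movie, hrf = hrf_spec(), gate = 0.01,
                    fine = TRUE, control = list(maxit = 400, reltol = 1e-6),
                    verbose = FALSE) {
  stopifnot(is.matrix(data), inherits(grid, "search_grid"))
  nv <- ncol(data)
  ctx <- model_context(movie, hrf)
  degen <- attr(data, "degenerate_vertices")
  if (is.null(degen)) degen <- rep(FALSE, nv)
  out <- data.frame(vertex_id = seq_len(nv), x0 = NA_real_, y0 = NA_real_,
                    sigma = NA_real_, beta1 = NA_real_, beta0 = NA_real_,
                    r2 = NA_real_, stage = "failed",
                    stringsAsFactors = FALSE)
  for (v in seq_len(nv)) {
    if (verbose && v %% 50 == 0) message("fit_map: vertex ", v, "/", nv)
    if (degen[v]) next
    y <- data[, v]
    cf <- coarse_fit(y, grid, gate = gate)
    if (cf$failed || !cf$passed_gate) next
    if (fine) {
      ff <- fine_fit(y, cf$params, movie, hrf, control = control, ctx = ctx)
    } else {
      ff <- list(params = cf$params, r_squared = cf$r_squared,
                 stage = "coarse-only")
    }
    pred <- predict_fast(ff$params$x0, ff$params$y0, ff$params$sigma, ctx)
    if (is.null(pred)) next
    betas <- fit_betas(y, as.vector(pred))
    out$x0[v] <- ff$params$x0
    out$y0[v] <- ff$params$y0
    out$sigma[v] <- ff$params$sigma
    out$beta1[v] <- betas[["beta1"]]
    out$beta0[v] <- betas[["beta0"]]
    out$r2[v] <- ff$r_squared
    out$stage[v] <- ff$stage
  }
  out
}

#' Write / read a per-vertex fit table as TSV
#' @param fits Data frame from [fit_map()].
#' @param path File path.
#' @return `path` (write) or the fit table (read).
#' @export
write_fits_tsv <- function(fits, path) {
  utils::write.table(fits, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fits_tsv
#' @export
read_fits_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
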