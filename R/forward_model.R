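# Gaussian pRF forward model: profile x aperture overlap, HRF convolution.

#' pRF parameter triple
#'
#' @param x0,y0 Centre of the population receptive field in visual-field
#'   coordinates (degrees; x rightward, y upward, origin at fixation).
#' @param sigma Standard deviation of the isotropic 2D Gaussian (degrees);
#'   must be positive.
#' @return An object of class `prf_params`.
#' @export
prf_params <- function(x0, y0, sigma) {
  stopifnot(is.finite(x0), is.finite(y0), is.finite(sigma))
  if (sigma <= 0) stop("'sigma' must be positive")
  structure(list(x0 = x0, y0 = y0, sigma = sigma), class = "prf_params")
}

#' Gaussian pRF profile on the aperture pixel grid
#'
#' Evaluates the unnormalised isotropic Gaussian
#' `exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2))` at every pixel centre of
#' the aperture grid. The peak value is 1 when the centre falls on a pixel.
#'
#' @param params A [prf_params()].
#' @param geometry An `aperture_movie`, or a list with `n_px` and
#'   `aperture_diameter_deg`.
#' @return A px x px weight matrix (same indexing as aperture masks).
#' @export
prf_profile <- function(params, geometry) {
  stopifnot(inherits(params, "prf_params"))
  g <- pixel_grids(geometry$n_px, geometry$aperture_diameter_deg)
  exp(-((g$x - params$x0)^2 + (g$y - params$y0)^2) / (2 * params$sigma^2))
}

#' Frame-by-frame neural response of a pRF to an aperture movie
#'
#' Multiplies each binary stimulus frame with the pRF profile and sums over
#' all pixels, giving the modelled (pre-haemodynamic) response per frame.
#'
#' @param profile A px x px weight matrix from [prf_profile()].
#' @param movie An `aperture_movie` with the same grid.
#' @return Numeric vector of length `n_frames(movie)`; zero on blank frames.
#' @export
neural_response <- function(profile, movie) {
  stopifnot(inherits(movie, "aperture_movie"))
  n_px <- movie$n_px
  if (!identical(dim(profile), c(n_px, n_px))) {
    stop("profile geometry does not match the movie mask grid")
  }
  nf <- dim(movie$frames)[3]
  as.vector(crossprod(matrix(movie$frames, n_px * n_px, nf),
                      as.vector(profile)))
}

#' Canonical double-gamma HRF specification
#'
#' Parameters of the canonical haemodynamic response used to convolve
#' modelled neural responses: a gamma density peaking ~5 s after stimulus
#' onset minus a scaled, later gamma density modelling the undershoot.
#'
#' @param peak_delay_s Delay of the response peak gamma (seconds).
#' @param undershoot_delay_s Delay of the undershoot gamma (seconds).
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions (scale
#'   parameters, seconds).
#' @param peak_undershoot_ratio Amplitude of the undershoot relative to the
#'   peak (subtracted).
#' @param duration_s Kernel support (seconds); long enough that the tail is
#'   negligible.
#' @param dt_s Sampling interval of the kernel (seconds); normally the TR.
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     peak_undershoot_ratio = 1 / 6,
                     duration_s = 32, dt_s = 1) {
  stopifnot(peak_delay_s > 0, undershoot_delay_s > 0,
            peak_dispersion > 0, undershoot_dispersion > 0,
            peak_undershoot_ratio >= 0, duration_s > 0, dt_s > 0)
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 duration_s = duration_s, dt_s = dt_s),
            class = "hrf_spec")
}

#' Sampled double-gamma HRF kernel
#'
#' @param spec An [hrf_spec()].
#' @return Numeric vector: the kernel sampled at `0, dt_s, 2 dt_s, ...,
#'   duration_s`, scaled to a peak of 1. Causal: the value at t = 0 is 0.
#' @export
hrf_kernel <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  t <- seq(0, spec$duration_s, by = spec$dt_s)
  h <- stats::dgamma(t, shape = spec$peak_delay_s / spec$peak_dispersion,
                     scale = spec$peak_dispersion) -
    spec$peak_undershoot_ratio *
      stats::dgamma(t, shape = spec$undershoot_delay_s / spec$undershoot_dispersion,
                    scale = spec$undershoot_dispersion)
  h / max(h)
}

# Causal zero-padded convolution truncated to the input length.
convolve_causal <- function(x, kernel) {
  n <- length(x)
  stats::convolve(c(x, numeric(length(kernel))), rev(kernel),
                  type = "open")[seq_len(n)]
}

# Standardize to mean 0, sample SD 1; returns zeros flagged degenerate when
# the variance vanishes.
zscore <- function(x, tol = 1e-12) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < tol) {
    return(structure(numeric(length(x)), degenerate = TRUE))
  }
  structure((x - mean(x)) / s, degenerate = FALSE)
}

#' Is a prediction (or preprocessed series) degenerate?
#'
#' Degenerate series (zero variance, e.g. a pRF with no stimulus overlap)
#' are represented as all-zero vectors carrying a `degenerate` attribute so
#' that fitting loops can skip them without raising errors.
#'
#' @param x A vector returned by [predict_timeseries()], [zscore] users, or
#'   [detrend_zscore()].
#' @return Logical scalar.
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

#' Predicted BOLD time series for a pRF
#'
#' Forward model: neural response (profile x mask overlap per frame),
#' causal convolution with the HRF kernel (zero-padded, truncated to the
#' movie length), then z-standardisation. The movie should exclude dummy
#' frames.
#'
#' @param params A [prf_params()].
#' @param movie An `aperture_movie` (without dummies).
#' @param hrf An [hrf_spec()].
#' @return Z-scored numeric vector of length `n_frames(movie)` (mean 0,
#'   SD 1), or an all-zero vector flagged via [is_degenerate()] when the pRF
#'   does not overlap the stimulated region.
#' @export
predict_timeseries <- function(params, movie, hrf = hrf_spec()) {
  nr <- neural_response(prf_profile(params, movie), movie)
  zscore(convolve_causal(nr, hrf_kernel(hrf)))
}

# Precomputed quantities for repeated forward-model evaluation on a fixed
# movie/HRF: flattened pixel coordinates, frame matrix, and the causal
# convolution operator as a lower-triangular Toeplitz matrix.
model_context <- function(movie, hrf = hrf_spec()) {
  g <- pixel_grids(movie$n_px, movie$aperture_diameter_deg)
  fm <- frame_matrix(movie)
  nf <- nrow(fm)
  k <- hrf_kernel(hrf)
  cm <- matrix(0, nf, nf)
  for (j in seq_len(nf)) {
    i <- j + seq_along(k) - 1L
    keep <- i <= nf
    cm[i[keep], j] <- k[keep]
  }
  list(px = as.vector(g$x), py = as.vector(g$y), fm = fm, convmat = cm,
       n_frames = nf)
}

# Fast z-scored prediction from a model context; NULL when degenerate.
predict_fast <- function(x0, y0, sigma, ctx) {
  w <- exp(-((ctx$px - x0)^2 + (ctx$py - y0)^2) / (2 * sigma^2))
  pred <- ctx$convmat %*% (ctx$fm %*% w)
  s <- stats::sd(pred)
  if (!is.finite(s) || s < 1e-12) return(NULL)
  (pred - mean(pred)) / s
}
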