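# Time-series conditioning: detrend, z-score, run averaging, low-pass.

#' Multi-run BOLD time-series container
#'
#' @param data Numeric array of dimension runs x time x vertices.
#' @param tr_s Repetition time (sampling interval) in seconds.
#' @param run_ids Optional run labels (default `run1..runK`).
#' @return An object of class `timeseries_set`.
#' @export
timeseries_set <- function(data, tr_s = 1, run_ids = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, tr_s > 0,
            all(is.finite(data)))
  if (is.null(run_ids)) run_ids <- paste0("run", seq_len(dim(data)[1]))
  stopifnot(length(run_ids) == dim(data)[1])
  structure(list(data = data, tr_s = tr_s, run_ids = run_ids),
            class = "timeseries_set")
}

#' @export
print.timeseries_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("timeseries_set: %d runs x %d volumes x %d vertices, TR %g s\n",
              d[1], d[2], d[3], x$tr_s))
  invisible(x)
}

#' Linear detrend and z-standardisation of one series
#'
#' Removes the least-squares line and scales the residual to mean 0, SD 1.
#' A series whose residual variance vanishes (e.g. an exact ramp) is
#' returned as zeros flagged via [is_degenerate()].
#'
#' @param series Numeric vector, length >= 3.
#' @return Detrended, z-scored vector with a `degenerate` attribute.
#' @export
detrend_zscore <- function(series) {
  n <- length(series)
  if (n < 3) stop("series too short to detrend (need length >= 3)")
  t <- seq_len(n) - (n + 1) / 2            # centred regressor
  slope <- sum(t * series) / sum(t * t)
  resid <- series - mean(series) - slope * t
  zscore(resid)
}

#' Detrend and z-score every run and vertex of a set
#'
#' Applies [detrend_zscore()] per run and vertex. Degenerate series are
#' propagated as flagged zeros; the per-vertex flag (`TRUE` if any run is
#' degenerate) is attached as the attribute `degenerate_vertices`.
#'
#' @param set A [timeseries_set()].
#' @return A `timeseries_set` of the same shape.
#' @export
preprocess_runs <- function(set) {
  stopifnot(inherits(set, "timeseries_set"))
  d <- dim(set$data)
  out <- set$data
  degen <- matrix(FALSE, d[1], d[3])
  for (r in seq_len(d[1])) {
    for (v in seq_len(d[3])) {
      z <- detrend_zscore(set$data[r, , v])
      out[r, , v] <- z
      degen[r, v] <- is_degenerate(z)
    }
  }
  res <- timeseries_set(out, set$tr_s, set$run_ids)
  attr(res, "degenerate_vertices") <- apply(degen, 2, any)
  res
}

#' Average runs of a time-series set
#'
#' Arithmetic mean across runs per time point and vertex. Runs should
#' already be detrended and z-scored ([preprocess_runs()]).
#'
#' @param set A [timeseries_set()].
#' @return A time x vertices matrix; the `degenerate_vertices` attribute of
#'   `set` (if any) is carried over.
#' @export
average_runs <- function(set) {
  stopifnot(inherits(set, "timeseries_set"))
  d <- dim(set$data)
  if (d[1] == 1) warning("single run: averaging is the identity")
  out <- apply(set$data, c(2, 3), mean)
  attr(out, "degenerate_vertices") <- attr(set, "degenerate_vertices")
  out
}

# Discrete Gaussian kernel, truncated at +/- 3 SD, renormalised to unit sum.
gaussian_kernel <- function(kernel_sd_s, tr_s) {
  sd_samp <- kernel_sd_s / tr_s
  half <- max(1L, ceiling(3 * sd_samp))
  k <- stats::dnorm(seq(-half, half), sd = sd_samp)
  k / sum(k)
}

#' Gaussian temporal low-pass filter
#'
#' Convolves each series with a discrete Gaussian of standard deviation
#' `kernel_sd_s` seconds (truncated at +/-3 SD and renormalised to unit sum),
#' using reflection padding so endpoints are not attenuated. Output length
#' equals input length.
#'
#' @param series Numeric vector, or a time x vertices matrix (filtered
#'   column-wise).
#' @param kernel_sd_s Kernel standard deviation in seconds (> 0).
#' @param tr_s Sampling interval in seconds.
#' @return Filtered series of the same shape.
#' @export
gaussian_lowpass <- function(series, kernel_sd_s, tr_s = 1) {
  if (!is.numeric(kernel_sd_s) || kernel_sd_s <= 0) {
    stop("'kernel_sd_s' must be positive")
  }
  k <- gaussian_kernel(kernel_sd_s, tr_s)
  half <- (length(k) - 1L) / 2L
  filt1 <- function(y) {
    n <- length(y)
    if (half >= n) stop("kernel wider than the series")
    pad <- c(y[(half + 1):2], y, y[(n - 1):(n - half)])
    as.numeric(stats::filter(pad, k, sides = 2))[(half + 1):(half + n)]
  }
  if (is.matrix(series)) {
    out <- apply(series, 2, filt1)
    dimnames(out) <- dimnames(series)
    out
  } else {
    filt1(series)
  }
}
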