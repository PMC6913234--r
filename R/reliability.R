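# Split-half reliability, Spearman-Brown noise ceiling, normalized fits.

#' Split-half correlation per vertex
#'
#' Splits the runs into even- and odd-numbered runs (by run order index),
#' averages each half, and returns the Pearson correlation between the two
#' half averages for every vertex. Runs should already be detrended and
#' z-scored ([preprocess_runs()]).
#'
#' @param set A [timeseries_set()] with at least 2 runs.
#' @param split `"even-odd"` (default) or `"random"`; a random split
#'   requires `seed`.
#' @param seed Integer seed for the random split.
#' @return Numeric vector of per-vertex correlations; `NA` where a half
#'   average is degenerate.
#' @export
split_half_r <- function(set, split = c("even-odd", "random"), seed = NULL) {
  stopifnot(inherits(set, "timeseries_set"))
  split <- match.arg(split)
  n_runs <- dim(set$data)[1]
  if (n_runs < 2) stop("split-half reliability needs at least 2 runs")
  idx <- seq_len(n_runs)
  if (split == "even-odd") {
    half_a <- idx[idx %% 2 == 1]
    half_b <- idx[idx %% 2 == 0]
  } else {
    if (is.null(seed)) stop("random split requires a seed")
    set.seed(seed)
    perm <- sample(idx)
    half_a <- perm[seq_len(floor(n_runs / 2))]
    half_b <- setdiff(perm, half_a)
  }
  mean_over_runs <- function(which_runs) {
    apply(set$data[which_runs, , , drop = FALSE], c(2, 3), mean)
  }
  a <- mean_over_runs(half_a)
  b <- mean_over_runs(half_b)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  r <- colSums(ac * bc) / den
  r[!is.finite(r)] <- NA_real_
  r
}

#' Spearman-Brown prophecy correction
#'
#' Projects the split-half correlation to the reliability of the full-run
#' average: `r_obs = 2 r' / (1 + r')` (doubling factor, i.e. two halves).
#'
#' @param r_split Split-half correlation(s) in `[-1, 1]`.
#' @return Corrected reliability; `NA` at `r_split = -1` (undefined).
#' @export
spearman_brown <- function(r_split) {
  if (any(abs(r_split) > 1 + 1e-12, na.rm = TRUE)) {
    stop("'r_split' must lie in [-1, 1]")
  }
  out <- 2 * r_split / (1 + r_split)
  out[!is.na(r_split) & r_split == -1] <- NA_real_
  out
}

#' Per-vertex noise ceiling
#'
#' Composes [split_half_r()] and [spearman_brown()]. With predictor
#' reliability and the hypothetical model-data correlation both assumed to
#' be 1, the maximum observable squared correlation (the noise ceiling) is
#' the Spearman-Brown-corrected reliability itself. Non-positive
#' reliabilities leave the ceiling undefined (`NA`) rather than clamped;
#' the count of such vertices is attached as attribute `n_undefined`.
#'
#' @inheritParams split_half_r
#' @return Data frame `vertex_id`, `r_split`, `r_obs`, `ceiling`.
#' @export
noise_ceiling_map <- function(set, split = c("even-odd", "random"),
                              seed = NULL) {
  r_split <- split_half_r(set, split = split, seed = seed)
  r_obs <- spearman_brown(r_split)
  ceiling <- ifelse(!is.na(r_obs) & r_obs > 0, r_obs, NA_real_)
  out <- data.frame(vertex_id = seq_along(r_split), r_split = r_split,
                    r_obs = r_obs, ceiling = ceiling)
  attr(out, "n_undefined") <- sum(is.na(ceiling))
  out
}

#' Noise-ceiling-normalized goodness-of-fit
#'
#' Divides the achieved R-squared by the noise ceiling. Values can exceed 1
#' under sampling noise; they are not clipped, but ratios above 1.5 are
#' flagged in the `flagged_high` attribute. An undefined ceiling propagates
#' as `NA`.
#'
#' @param r_squared Achieved squared correlation(s).
#' @param ceiling Noise ceiling(s) from [noise_ceiling_map()].
#' @return Normalized R-squared vector with attribute `flagged_high`.
#' @export
normalized_fit <- function(r_squared, ceiling) {
  out <- r_squared / ceiling
  out[is.na(ceiling)] <- NA_real_
  structure(out, flagged_high = !is.na(out) & out > 1.5)
}
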