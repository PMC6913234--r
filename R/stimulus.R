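# Sweeping-bar stimulus design and binary aperture movies.

#' Sweeping-bar mapping design
#'
#' Describes the bar-mapping protocol: a bar of fixed width sweeps across a
#' circular aperture in a fixed number of equally timed steps, the sweep
#' direction rotating clockwise between sweeps, with baseline (blank) blocks
#' inserted after designated sweeps and optional dummy volumes at the start.
#'
#' The default protocol is eight 25-step sweeps (one frame per second),
#' starting bottom-to-top and rotating 45 degrees clockwise per sweep, with a
#' 25 s baseline after sweeps 4 and 8 and 10 dummy frames, inside a circular
#' aperture 19 degrees in diameter.
#'
#' Two stepping conventions are supported. `step_mode = "full-coverage"`
#' (the default) sets the jump between consecutive bar positions to
#' `aperture_diameter_deg / steps_per_sweep` so that the sweep traverses the
#' whole aperture. `step_mode = "literal"` uses `step_deg` exactly (default
#' 0.38 degrees per step), which with 25 steps maps only the central strip.
#'
#' @param aperture_diameter_deg Diameter of the circular stimulated region
#'   (degrees of visual angle).
#' @param bar_width_deg Bar width (degrees).
#' @param steps_per_sweep Number of bar positions per sweep.
#' @param n_sweeps Number of sweeps per run.
#' @param step_mode `"full-coverage"` or `"literal"`; see Details.
#' @param step_deg Step size in degrees used in `"literal"` mode.
#' @param first_sweep_direction_deg Direction of motion of the first sweep,
#'   measured clockwise in degrees from bottom-to-top (0 = upward motion).
#' @param rotation_per_sweep_deg Clockwise rotation of the sweep direction
#'   between consecutive sweeps (degrees).
#' @param baseline_after_sweeps Integer sweep indices after which a baseline
#'   block is inserted.
#' @param baseline_duration_s Duration of each baseline block (seconds).
#' @param n_dummies Number of dummy (blank) frames before the first sweep.
#' @param mask_resolution_px Side length of the square binary mask in pixels.
#' @param frame_duration_s Duration of one frame (seconds); equals the TR
#'   for designs where the bar jumps once per volume.
#' @param hole_radius_deg Radius of the central blank hole around fixation
#'   carved out of every bar frame (degrees); 0 disables it.
#'
#' @return An object of class `bar_design`.
#' @seealso [generate_apertures()], [bar_mask()]
#' @export
bar_design <- function(aperture_diameter_deg = 19,
                       bar_width_deg = 0.53,
                       steps_per_sweep = 25,
                       n_sweeps = 8,
                       step_mode = c("full-coverage", "literal"),
                       step_deg = 0.38,
                       first_sweep_direction_deg = 0,
                       rotation_per_sweep_deg = 45,
                       baseline_after_sweeps = c(4, 8),
                       baseline_duration_s = 25,
                       n_dummies = 10,
                       mask_resolution_px = 100,
                       frame_duration_s = 1,
                       hole_radius_deg = 0.53) {
  step_mode <- match.arg(step_mode)
  stopifnot(
    aperture_diameter_deg > 0, bar_width_deg > 0,
    steps_per_sweep >= 1, n_sweeps >= 1, step_deg > 0,
    baseline_duration_s > 0, n_dummies >= 0,
    mask_resolution_px >= 16, frame_duration_s > 0,
    hole_radius_deg >= 0
  )
  if (length(baseline_after_sweeps) &&
      any(baseline_after_sweeps < 1 | baseline_after_sweeps > n_sweeps)) {
    stop("'baseline_after_sweeps' indices must lie in 1..n_sweeps")
  }
  design <- list(
    aperture_diameter_deg = aperture_diameter_deg,
    bar_width_deg = bar_width_deg,
    steps_per_sweep = as.integer(steps_per_sweep),
    n_sweeps = as.integer(n_sweeps),
    step_mode = step_mode,
    step_deg = step_deg,
    first_sweep_direction_deg = first_sweep_direction_deg,
    rotation_per_sweep_deg = rotation_per_sweep_deg,
    baseline_after_sweeps = as.integer(baseline_after_sweeps),
    baseline_duration_s = baseline_duration_s,
    n_dummies = as.integer(n_dummies),
    mask_resolution_px = as.integer(mask_resolution_px),
    frame_duration_s = frame_duration_s,
    hole_radius_deg = hole_radius_deg
  )
  class(design) <- "bar_design"
  design
}

#' Effective step size of a bar design, in degrees
#' @param design A [bar_design()].
#' @return Step size between consecutive bar positions (degrees).
#' @export
bar_step_deg <- function(design) {
  if (design$step_mode == "full-coverage") {
    design$aperture_diameter_deg / design$steps_per_sweep
  } else {
    design$step_deg
  }
}

# Pixel-centre coordinates along one axis of the mask grid.
# The grid spans the bounding square of the circular aperture; x runs
# rightward, y upward, with the origin at fixation.
pixel_axis <- function(n_px, diameter_deg) {
  dpp <- diameter_deg / n_px
  (seq_len(n_px) - 0.5) * dpp - diameter_deg / 2
}

# Full pixel-centre grids as px-by-px matrices (X varies along rows,
# Y along columns), matching the mask storage convention mask[ix, iy].
pixel_grids <- function(n_px, diameter_deg) {
  ax <- pixel_axis(n_px, diameter_deg)
  list(
    x = matrix(ax, n_px, n_px),
    y = matrix(ax, n_px, n_px, byrow = TRUE),
    deg_per_px = diameter_deg / n_px
  )
}

#' Binary mask of one bar position
#'
#' Computes the binary aperture mask of the bar at a given step of a sweep.
#' A pixel is set iff its centre lies inside the bar strip, inside the
#' circular aperture, and outside the central fixation hole.
#'
#' @param step_index Bar position within the sweep, 1-based
#'   (`1..steps_per_sweep`).
#' @param orientation_deg Direction of sweep motion, clockwise degrees from
#'   bottom-to-top; the bar itself is perpendicular to this direction.
#' @param design A [bar_design()].
#' @return A `mask_resolution_px` x `mask_resolution_px` 0/1 matrix; element
#'   `[i, j]` corresponds to visual-field position `(x[i], y[j])` with x
#'   rightward and y upward.
#' @export
bar_mask <- function(step_index, orientation_deg, design) {
  stopifnot(inherits(design, "bar_design"))
  if (length(step_index) != 1L || step_index < 1L ||
      step_index > design$steps_per_sweep || step_index != round(step_index)) {
    stop("'step_index' must be an integer in 1..steps_per_sweep")
  }
  n_px <- design$mask_resolution_px
  g <- pixel_grids(n_px, design$aperture_diameter_deg)
  radius <- design$aperture_diameter_deg / 2
  step <- bar_step_deg(design)
  # Bar-centre position along the motion axis, centred on fixation.
  pos <- (step_index - (design$steps_per_sweep + 1) / 2) * step
  phi <- orientation_deg * pi / 180
  # Unit motion vector: clockwise rotation of (0, 1) by phi.
  proj <- g$x * sin(phi) + g$y * cos(phi)
  r2 <- g$x^2 + g$y^2
  mask <- (abs(proj - pos) <= design$bar_width_deg / 2) &
    (r2 <= radius^2)
  if (design$hole_radius_deg > 0) {
    mask <- mask & (r2 >= design$hole_radius_deg^2)
  }
  storage.mode(mask) <- "double"
  mask
}

#' Generate the aperture movie for a full run
#'
#' Builds the time-ordered stack of binary masks for one mapping run:
#' optional dummy frames, then the sweeps in order with baseline blocks
#' inserted after the designated sweeps. Sweep `k` moves in the direction
#' `first_sweep_direction_deg + (k - 1) * rotation_per_sweep_deg` (clockwise
#' from bottom-to-top). Dummy and baseline frames are all-zero.
#'
#' @param design A [bar_design()].
#' @param include_dummies Include the `n_dummies` leading blank frames?
#'   Model fitting operates on movies without dummies.
#' @return An object of class `aperture_movie`: a list with `frames`
#'   (px x px x n_frames 0/1 array), `deg_per_px`, `frame_duration_s`, `n_px`,
#'   `aperture_diameter_deg` and `schedule`, a data frame with one row per
#'   frame (`frame`, `label` in dummy/bar/baseline, `sweep`, `step`,
#'   `orientation_deg`).
#' @export
generate_apertures <- function(design = bar_design(), include_dummies = TRUE) {
  stopifnot(inherits(design, "bar_design"))
  n_px <- design$mask_resolution_px
  n_baseline <- as.integer(round(design$baseline_duration_s /
                                   design$frame_duration_s))
  frames_list <- list()
  sched <- list()
  blank <- matrix(0, n_px, n_px)
  add <- function(mask, label, sweep = NA_integer_, step = NA_integer_,
                  orientation = NA_real_) {
    frames_list[[length(frames_list) + 1L]] <<- mask
    sched[[length(sched) + 1L]] <<- data.frame(
      label = label, sweep = sweep, step = step, orientation_deg = orientation
    )
  }
  if (include_dummies && design$n_dummies > 0) {
    for (i in seq_len(design$n_dummies)) add(blank, "dummy")
  }
  for (k in seq_len(design$n_sweeps)) {
    ori <- (design$first_sweep_direction_deg +
              (k - 1) * design$rotation_per_sweep_deg) %% 360
    for (s in seq_len(design$steps_per_sweep)) {
      add(bar_mask(s, ori, design), "bar", k, s, ori)
    }
    if (k %in% design$baseline_after_sweeps) {
      for (i in seq_len(n_baseline)) add(blank, "baseline", k)
    }
  }
  n_frames <- length(frames_list)
  frames <- array(unlist(frames_list, use.names = FALSE),
                  dim = c(n_px, n_px, n_frames))
  schedule <- do.call(rbind, sched)
  schedule <- cbind(frame = seq_len(n_frames), schedule)
  movie <- list(
    frames = frames,
    n_px = n_px,
    deg_per_px = design$aperture_diameter_deg / n_px,
    aperture_diameter_deg = design$aperture_diameter_deg,
    frame_duration_s = design$frame_duration_s,
    schedule = schedule
  )
  class(movie) <- "aperture_movie"
  movie
}

#' Drop leading dummy frames from an aperture movie
#' @param movie An [generate_apertures()] result.
#' @return The movie restricted to non-dummy frames.
#' @export
drop_dummies <- function(movie) {
  stopifnot(inherits(movie, "aperture_movie"))
  keep <- movie$schedule$label != "dummy"
  movie$frames <- movie$frames[, , keep, drop = FALSE]
  movie$schedule <- movie$schedule[keep, , drop = FALSE]
  movie$schedule$frame <- seq_len(nrow(movie$schedule))
  rownames(movie$schedule) <- NULL
  movie
}

#' Number of frames in an aperture movie
#' @param movie An `aperture_movie`.
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

# Frames flattened to an n_frames x n_pixels matrix (column-major pixel
# order, consistent with as.vector() of a profile matrix).
frame_matrix <- function(movie) {
  n_px <- movie$n_px
  nf <- dim(movie$frames)[3]
  t(matrix(movie$frames, n_px * n_px, nf))
}

#' @export
print.aperture_movie <- function(x, ...) {
  cat(sprintf("aperture_movie: %d frames, %dx%d px, %.4g deg/px, %g s/frame\n",
              n_frames(x), x$n_px, x$n_px, x$deg_per_px, x$frame_duration_s))
  print(table(x$schedule$label))
  invisible(x)
}

#' Write an aperture movie to NIfTI
#'
#' Stores the mask stack as a px x px x n_frames NIfTI volume (requires the
#' RNifti package) together with a JSON sidecar holding `deg_per_px`,
#' `frame_duration_s` and the frame schedule.
#'
#' @param movie An `aperture_movie`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_apertures_nifti <- function(movie, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_apertures_nifti() requires the RNifti package")
  }
  RNifti::writeNifti(movie$frames, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(deg_per_px = movie$deg_per_px,
         frame_duration_s = movie$frame_duration_s,
         schedule = movie$schedule),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
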