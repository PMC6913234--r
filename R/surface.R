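# Mesh-based map operations: cortical magnification, smoothing, binned
# summaries with bootstrap CIs, and between-map comparison statistics.

#' Triangulated cortical patch with a pRF map
#'
#' @param vertex_positions n x 2 matrix of vertex coordinates in mm
#'   (flattened patch plane).
#' @param triangles m x 3 integer matrix of vertex indices (1-based).
#' @param fits Optional per-vertex pRF table aligned by row with
#'   `vertex_positions` (columns at least `x0`, `y0`; typically a
#'   [fit_map()] result).
#' @return An object of class `retino_mesh`.
#' @export
retino_mesh <- function(vertex_positions, triangles, fits = NULL) {
  vertex_positions <- as.matrix(vertex_positions)
  triangles <- as.matrix(triangles)
  stopifnot(ncol(vertex_positions) == 2, ncol(triangles) == 3,
            max(triangles) <= nrow(vertex_positions), min(triangles) >= 1)
  if (!is.null(fits)) stopifnot(nrow(fits) == nrow(vertex_positions))
  structure(list(vertex_positions = vertex_positions,
                 triangles = triangles, fits = fits),
            class = "retino_mesh")
}

#' @export
print.retino_mesh <- function(x, ...) {
  cat(sprintf("retino_mesh: %d vertices, %d triangles%s\n",
              nrow(x$vertex_positions), nrow(x$triangles),
              if (is.null(x$fits)) "" else ", pRF map attached"))
  invisible(x)
}

# Adjacency list (unique neighbours per vertex) from the triangle list.
mesh_neighbors <- function(mesh) {
  n <- nrow(mesh$vertex_positions)
  tri <- mesh$triangles
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  nb <- vector("list", n)
  both <- rbind(edges, edges[, 2:1])
  sp <- split(both[, 2], both[, 1])
  for (k in names(sp)) nb[[as.integer(k)]] <- sort(unique(sp[[k]]))
  nb
}

# Vertices incident to a boundary edge (an edge used by only one triangle).
boundary_vertices <- function(mesh) {
  tri <- mesh$triangles
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  counts <- table(key)
  bkey <- names(counts)[counts == 1]
  bverts <- unique(as.integer(unlist(strsplit(bkey, " "))))
  sort(bverts)
}

#' Area of the polygon through an ordered point list
#'
#' Absolute shoelace area of the polygon whose vertices are the given
#' points in order (typically a vertex's one-ring neighbours ordered around
#' it).
#'
#' @param points n x 2 matrix of coordinates, n >= 3, in traversal order.
#' @return Non-negative area; `NA` for fewer than 3 points.
#' @export
neighbor_polygon_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) return(NA_real_)
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# One-ring neighbours of vertex v ordered by angle around v in the patch
# plane (required for a consistent shoelace traversal).
ordered_ring <- function(mesh, v, nb = NULL) {
  if (is.null(nb)) nb <- mesh_neighbors(mesh)
  ring <- nb[[v]]
  if (length(ring) < 3) return(integer(0))
  p0 <- mesh$vertex_positions[v, ]
  d <- sweep(mesh$vertex_positions[ring, , drop = FALSE], 2, p0)
  ring[order(atan2(d[, 2], d[, 1]))]
}

#' Cortical magnification factor map
#'
#' For every interior vertex, forms the polygon of its one-ring neighbours
#' (ordered by angle around the vertex in the cortical plane), computes the
#' cortical area of that polygon and the visual-field area of the polygon
#' formed by the same neighbours' pRF centres, and returns
#' `CMF = sqrt(cortical area) / sqrt(visual area)` in mm/degree.
#'
#' Boundary vertices, vertices with fewer than 3 neighbours, vertices with
#' any neighbour lacking a pRF estimate, and zero visual areas yield `NA`.
#' Vertices whose visual polygon is traversed with inconsistent winding
#' (sign changes in the cross products, indicating a self-intersecting or
#' folded polygon) are flagged in the attribute `inconsistent_winding`.
#'
#' @param mesh A [retino_mesh()] with `fits` containing `x0`, `y0`.
#' @return Numeric per-vertex CMF vector with attribute
#'   `inconsistent_winding`.
#' @export
cmf_map <- function(mesh) {
  stopifnot(inherits(mesh, "retino_mesh"))
  if (is.null(mesh$fits)) stop("mesh carries no pRF map")
  n <- nrow(mesh$vertex_positions)
  nb <- mesh_neighbors(mesh)
  boundary <- rep(FALSE, n)
  boundary[boundary_vertices(mesh)] <- TRUE
  cmf <- rep(NA_real_, n)
  winding <- rep(FALSE, n)
  vx <- mesh$fits$x0
  vy <- mesh$fits$y0
  for (v in seq_len(n)) {
    if (boundary[v]) next
    ring <- ordered_ring(mesh, v, nb)
    if (length(ring) < 3) next
    if (anyNA(vx[ring]) || anyNA(vy[ring])) next
    cort <- mesh$vertex_positions[ring, , drop = FALSE]
    vis <- cbind(vx[ring], vy[ring])
    a_cort <- neighbor_polygon_area(cort)
    a_vis <- neighbor_polygon_area(vis)
    if (!is.finite(a_vis) || a_vis <= 0) next
    cmf[v] <- sqrt(a_cort) / sqrt(a_vis)
    # winding consistency: cross products of consecutive edges should not
    # change sign for a convexly traversed (non-folded) polygon
    nxt <- c(seq_len(nrow(vis))[-1], 1L)
    e <- vis[nxt, , drop = FALSE] - vis
    cross <- e[, 1] * e[nxt, 2] - e[nxt, 1] * e[, 2]
    winding[v] <- length(unique(sign(cross[abs(cross) > 1e-12]))) > 1
  }
  structure(cmf, inconsistent_winding = winding)
}

#' Gaussian smoothing of a per-vertex map on a flat patch
#'
#' Replaces each vertex value by a Gaussian-weighted mean of values at
#' vertices within 3 SD (Euclidean distance in the patch plane), with
#' `SD = fwhm_mm / (2 sqrt(2 log 2))`. Undefined (`NA`) values are excluded
#' and the remaining weights renormalised.
#'
#' @param mesh A [retino_mesh()].
#' @param values Per-vertex numeric vector.
#' @param fwhm_mm Kernel full width at half maximum in mm (> 0).
#' @return Smoothed per-vertex vector.
#' @export
smooth_map <- function(mesh, values, fwhm_mm) {
  stopifnot(inherits(mesh, "retino_mesh"), fwhm_mm > 0,
            length(values) == nrow(mesh$vertex_positions))
  sd_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  pos <- mesh$vertex_positions
  d2 <- outer(pos[, 1], pos[, 1], "-")^2 + outer(pos[, 2], pos[, 2], "-")^2
  w <- exp(-d2 / (2 * sd_mm^2))
  w[d2 > (3 * sd_mm)^2] <- 0
  ok <- !is.na(values)
  w[, !ok] <- 0
  denom <- rowSums(w)
  vals <- values
  vals[!ok] <- 0
  out <- as.vector(w %*% vals) / denom
  out[denom == 0] <- NA_real_
  out
}

# Percentile bootstrap CI of a statistic; uses the current RNG stream.
boot_ci <- function(x, stat = mean, n_boot = 1000, level = 0.95) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boots <- if (identical(stat, mean)) {
    colMeans(matrix(x[idx], nrow = n))
  } else {
    apply(matrix(x[idx], nrow = n), 2, stat)
  }
  alpha <- (1 - level) / 2
  stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
}

#' Eccentricity-binned summary with bootstrap confidence intervals
#'
#' Bins per-vertex values into eccentricity bands (default 1-degree-wide
#' bands from 0.5 to 9.5 degrees; half-open `[lo, lo+width)`, final bin
#' closed) and summarises each bin with the mean (pRF size) or median
#' (other statistics), with a central bootstrap confidence interval
#' (default 1000 resamples, 95%). When `r_squared` and `r2_threshold` are
#' supplied, vertices at or below the threshold are excluded first — the
#' convention for pRF size and CMF summaries (threshold 0.15).
#'
#' @param ecc Per-vertex eccentricity (degrees).
#' @param values Per-vertex values to summarise; `NA`s are dropped.
#' @param stat `"mean"` or `"median"`.
#' @param r_squared Optional per-vertex goodness-of-fit used for exclusion.
#' @param r2_threshold Exclusion threshold: keep vertices with
#'   `r_squared > r2_threshold`. `NULL` disables filtering.
#' @param bin_start,bin_end,bin_width Bin layout in degrees.
#' @param n_boot,level Bootstrap resamples and CI level.
#' @return Data frame `bin_lo`, `bin_hi`, `n`, `value`, `ci_low`, `ci_high`,
#'   `empty`. Empty bins carry `NA` value and CI.
#' @export
bin_summarize <- function(ecc, values, stat = c("mean", "median"),
                          r_squared = NULL, r2_threshold = NULL,
                          bin_start = 0.5, bin_end = 9.5, bin_width = 1,
                          n_boot = 1000, level = 0.95) {
  stat <- match.arg(stat)
  stopifnot(length(ecc) == length(values))
  keep <- !is.na(values) & !is.na(ecc)
  if (!is.null(r2_threshold)) {
    stopifnot(length(r_squared) == length(values))
    keep <- keep & !is.na(r_squared) & r_squared > r2_threshold
  }
  ecc <- ecc[keep]; values <- values[keep]
  lo <- seq(bin_start, bin_end - bin_width, by = bin_width)
  hi <- lo + bin_width
  stat_fun <- if (stat == "mean") mean else stats::median
  out <- data.frame(bin_lo = lo, bin_hi = hi, n = 0L, value = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, empty = TRUE)
  for (i in seq_along(lo)) {
    in_bin <- ecc >= lo[i] & (if (i == length(lo)) ecc <= hi[i] else ecc < hi[i])
    x <- values[in_bin]
    out$n[i] <- length(x)
    if (length(x) == 0) next
    out$empty[i] <- FALSE
    out$value[i] <- stat_fun(x)
    if (length(x) >= 2) {
      ci <- boot_ci(x, stat = if (stat == "mean") mean else stats::median,
                    n_boot = n_boot, level = level)
      out$ci_low[i] <- ci[1]
      out$ci_high[i] <- ci[2]
    } else {
      out$ci_low[i] <- out$ci_high[i] <- out$value[i]
    }
  }
  out
}

#' Fisher-Lee circular correlation
#'
#' Rotation-invariant circular correlation coefficient between two angle
#' vectors: `sum_{i<j} sin(a_i - a_j) sin(b_i - b_j)` over the geometric
#' mean of the corresponding squared-sine sums.
#'
#' @param angles_a,angles_b Angles in radians, equal length >= 3.
#' @return Correlation in `[-1, 1]`; `NA` when fewer than 3 pairs or when
#'   either set of angles is degenerate (no spread).
#' @export
circular_corr <- function(angles_a, angles_b) {
  stopifnot(length(angles_a) == length(angles_b))
  if (length(angles_a) < 3) return(NA_real_)
  sa <- sin(outer(angles_a, angles_a, "-"))
  sb <- sin(outer(angles_b, angles_b, "-"))
  num <- sum(sa * sb) / 2
  den <- sqrt(sum(sa^2) / 2 * sum(sb^2) / 2)
  if (den < 1e-15) return(NA_real_)
  num / den
}

#' Compare two pRF maps above a goodness-of-fit threshold
#'
#' Restricts both fit tables to vertices exceeding the R-squared threshold
#' in BOTH maps, then correlates polar angle with the Fisher-Lee circular
#' correlation and eccentricity with Spearman's rank correlation.
#'
#' @param fit_a,fit_b [fit_map()] tables sharing `vertex_id`.
#' @param r2_threshold Inclusion threshold applied to both maps
#'   (default 0.1, the map-display convention).
#' @return List with `polar_r`, `ecc_rho`, `n_common`.
#' @export
compare_maps <- function(fit_a, fit_b, r2_threshold = 0.1) {
  m <- merge(fit_a, fit_b, by = "vertex_id", suffixes = c("_a", "_b"))
  ok <- !is.na(m$r2_a) & !is.na(m$r2_b) &
    m$r2_a > r2_threshold & m$r2_b > r2_threshold
  m <- m[ok, ]
  if (nrow(m) < 3) {
    return(list(polar_r = NA_real_, ecc_rho = NA_real_, n_common = nrow(m)))
  }
  pol_a <- atan2(m$y0_a, m$x0_a)
  pol_b <- atan2(m$y0_b, m$x0_b)
  ecc_a <- sqrt(m$x0_a^2 + m$y0_a^2)
  ecc_b <- sqrt(m$x0_b^2 + m$y0_b^2)
  list(polar_r = circular_corr(pol_a, pol_b),
       ecc_rho = stats::cor(ecc_a, ecc_b, method = "spearman"),
       n_common = nrow(m))
}
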