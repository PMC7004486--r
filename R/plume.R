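#' Static (time-averaged) plume field
#'
#' A smooth, stationary concentration field, typically the per-pixel time
#' average of a dynamic plume movie. Concentration values are dimensionless
#' (max-normalized). The grid is stored as a matrix indexed `[ix, iy]` where
#' `ix` runs along the flow (`x`) direction; pixel `(i, j)` covers the arena
#' square `[origin + (i-1)/px_per_cm, origin + i/px_per_cm)`.
#'
#' @param grid Numeric matrix `[nx, ny]` of non-negative finite values.
#' @param px_per_cm Spatial calibration, pixels per cm (default 1).
#' @param origin Arena coordinate (cm) of the grid corner at index `(1, 1)`.
#' @return An object of class `static_plume`.
#' @export
static_plume <- function(grid, px_per_cm = 1, origin = c(0, 0)) {
  if (!is.matrix(grid) || !is.numeric(grid)) {
    stop("`grid` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(grid) || any(!is.finite(grid)) || any(grid < 0)) {
    stop("`grid` values must be finite and >= 0", call. = FALSE)
  }
  stopifnot_finite(c(px_per_cm, origin), "static_plume calibration")
  if (px_per_cm <= 0) stop("px_per_cm must be > 0", call. = FALSE)
  structure(list(grid = grid, px_per_cm = px_per_cm,
                 origin = as.numeric(origin)),
            class = "static_plume")
}

#' Dynamic plume movie
#'
#' A stack of instantaneous concentration fields. Frames are stored as a 3-D
#' array `[ix, iy, t]` (x along the flow, y transverse, time last); frame
#' indices are 1-based at the interface. During sampling the movie loops
#' continuously (frame arithmetic is modulo `n_frames`).
#'
#' @param frames Numeric 3-D array `[nx, ny, n_frames]`, values finite and
#'   non-negative.
#' @param fps Frame rate in Hz. The reference 4-minute, 3600-frame movie
#'   implies 15 fps, the default used throughout.
#' @inheritParams static_plume
#' @return An object of class `dynamic_plume`.
#' @export
dynamic_plume <- function(frames, fps = 15, px_per_cm = 1, origin = c(0, 0)) {
  if (!is.array(frames) || length(dim(frames)) != 3L || !is.numeric(frames)) {
    stop("`frames` must be a numeric 3-D array [nx, ny, n_frames]",
         call. = FALSE)
  }
  if (anyNA(frames) || any(!is.finite(frames)) || any(frames < 0)) {
    stop("`frames` values must be finite and >= 0", call. = FALSE)
  }
  stopifnot_finite(c(fps, px_per_cm, origin), "dynamic_plume calibration")
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (px_per_cm <= 0) stop("px_per_cm must be > 0", call. = FALSE)
  structure(list(frames = frames, fps = fps, px_per_cm = px_per_cm,
                 origin = as.numeric(origin), n_frames = dim(frames)[3]),
            class = "dynamic_plume")
}

#' @export
print.static_plume <- function(x, ...) {
  cat(sprintf("<static_plume> %d x %d px @ %g px/cm, max %.3g\n",
              nrow(x$grid), ncol(x$grid), x$px_per_cm, max(x$grid)))
  invisible(x)
}

#' @export
print.dynamic_plume <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<dynamic_plume> %d frames of %d x %d px @ %g fps, %g px/cm (%.1f s)\n",
    d[3], d[1], d[2], x$fps, x$px_per_cm, d[3] / x$fps))
  invisible(x)
}

#' Time-average a plume movie
#'
#' Per-pixel arithmetic mean over all frames, producing the smooth static
#' field used for the low-complexity (deterministic) condition. Calibration
#' is copied from the movie.
#'
#' @param movie A [dynamic_plume()].
#' @return A [static_plume()].
#' @export
time_average <- function(movie) {
  stopifnot(inherits(movie, "dynamic_plume"))
  d <- dim(movie$frames)
  grid <- rowMeans(movie$frames, dims = 2)
  dim(grid) <- d[1:2]
  static_plume(grid, movie$px_per_cm, movie$origin)
}

# Map an arena coordinate to 1-based pixel indices, or NULL if off the grid.
pixel_index <- function(plume, point) {
  nx <- if (inherits(plume, "static_plume")) nrow(plume$grid) else
    dim(plume$frames)[1]
  ny <- if (inherits(plume, "static_plume")) ncol(plume$grid) else
    dim(plume$frames)[2]
  ix <- floor((point[1] - plume$origin[1]) * plume$px_per_cm) + 1
  iy <- floor((point[2] - plume$origin[2]) * plume$px_per_cm) + 1
  if (ix < 1 || ix > nx || iy < 1 || iy > ny) return(NULL)
  c(ix, iy)
}

#' Sample a plume at a point and time
#'
#' Nearest-pixel (point-source) sampling, no interpolation. For a dynamic
#' plume the frame is `(start_frame - 1 + floor(sim_time_s * fps)) mod
#' n_frames + 1`, so the movie loops continuously. Points outside the grid
#' return 0: sensors legitimately overhang the walls while the chassis center
#' stays inside.
#'
#' @param plume A [static_plume()] or [dynamic_plume()].
#' @param point Numeric `(x, y)` arena coordinate (cm).
#' @param sim_time_s Simulated time since trial start (ignored for static
#'   plumes).
#' @param start_frame 1-based frame at `sim_time_s = 0` (dynamic plumes).
#' @return Scalar concentration.
#' @export
sample_plume <- function(plume, point, sim_time_s = 0, start_frame = 1L) {
  stopifnot_finite(point, "point")
  idx <- pixel_index(plume, point)
  if (is.null(idx)) return(0)
  if (inherits(plume, "static_plume")) {
    return(plume$grid[idx[1], idx[2]])
  }
  it <- (start_frame - 1L + floor(sim_time_s * plume$fps)) %% plume$n_frames
  plume$frames[idx[1], idx[2], it + 1L]
}

#' Draw a random start frame
#'
#' Trials on a dynamic plume are randomized by starting the movie at a
#' uniformly drawn frame (the reference design draws between frames 1 and
#' 3600); the movie then loops. Uses R's RNG, so seed with [set.seed()] for
#' reproducibility. Static plumes always return 1.
#'
#' @param movie A [dynamic_plume()] (or [static_plume()], returning 1).
#' @return Integer frame index in `1:n_frames`.
#' @export
random_start_frame <- function(movie) {
  if (inherits(movie, "static_plume")) return(1L)
  stopifnot(inherits(movie, "dynamic_plume"))
  sample.int(movie$n_frames, 1L)
}

#' Probe statistics of a plume movie
#'
#' Extracts the pixel time series at each probe and reports its mean, sample
#' (n-1) standard deviation, SD/mean, and intermittency. Intermittency is the
#' fraction of time the series exceeds `threshold_frac` (default 4.4%) of the
#' time-averaged signal at a reference probe, conventionally placed 10 cm
#' downstream of the source on the centerline.
#'
#' @param movie A [dynamic_plume()] with at least 2 frames.
#' @param probes A list of `(x, y)` arena coordinates (or a single 2-vector).
#' @param ref_probe `(x, y)` coordinate of the reference probe.
#' @param threshold_frac Intermittency threshold as a fraction of the
#'   reference mean (default 0.044).
#' @return A data.frame with one row per probe: `x_cm`, `y_cm`, `mean`, `sd`,
#'   `sd_over_mean` (NA when the mean is 0), `intermittency`.
#' @export
probe_stats <- function(movie, probes, ref_probe, threshold_frac = 0.044) {
  stopifnot(inherits(movie, "dynamic_plume"))
  if (movie$n_frames < 2L) stop("need >= 2 frames for probe SD", call. = FALSE)
  if (!is.list(probes)) probes <- list(probes)
  series_at <- function(p) {
    idx <- pixel_index(movie, p)
    if (is.null(idx)) stop("probe (", p[1], ", ", p[2],
                           ") is outside the plume grid", call. = FALSE)
    movie$frames[idx[1], idx[2], ]
  }
  ref_mean <- mean(series_at(ref_probe))
  if (ref_mean <= 0) {
    stop("intermittency undefined: reference probe has zero mean signal",
         call. = FALSE)
  }
  thr <- threshold_frac * ref_mean
  rows <- lapply(probes, function(p) {
    s <- series_at(p)
    m <- mean(s)
    data.frame(x_cm = p[1], y_cm = p[2], mean = m, sd = stats::sd(s),
               sd_over_mean = if (m > 0) stats::sd(s) / m else NA_real_,
               intermittency = mean(s > thr))
  })
  do.call(rbind, rows)
}
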