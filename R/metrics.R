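#' Tracked path
#'
#' A time-ordered sequence of tracked positions: a body point per frame and,
#' optionally, a nose point (as exported by overhead video tracking, two
#' tracked points per frame). Simulated trajectories convert via
#' [as_tracked_path()].
#'
#' @param t_s Frame times in seconds (non-decreasing).
#' @param body_x,body_y Body-center coordinates (cm).
#' @param nose_x,nose_y Optional nose coordinates (cm).
#' @return A data.frame of class `tracked_path`.
#' @export
tracked_path <- function(t_s, body_x, body_y, nose_x = NULL, nose_y = NULL) {
  stopifnot_finite(c(t_s, body_x, body_y), "tracked_path")
  n <- length(t_s)
  if (length(body_x) != n || length(body_y) != n) {
    stop("t_s, body_x, body_y must have equal length", call. = FALSE)
  }
  if (is.unsorted(t_s)) stop("frames must be time-ordered", call. = FALSE)
  df <- data.frame(t_s = t_s, body_x = body_x, body_y = body_y)
  if (!is.null(nose_x)) {
    stopifnot_finite(c(nose_x, nose_y), "nose track")
    if (length(nose_x) != n || length(nose_y) != n) {
      stop("nose track must match frame count", call. = FALSE)
    }
    df$nose_x <- nose_x
    df$nose_y <- nose_y
  }
  class(df) <- c("tracked_path", "data.frame")
  df
}

has_nose <- function(path) all(c("nose_x", "nose_y") %in% names(path))

#' Convert a simulated trial to a tracked path
#'
#' The chassis center becomes the body point and the midpoint of the two
#' sensors (on the heading axis, one chassis radius ahead) becomes the nose
#' point. Baseline-phase ticks (the agent is stationary) are dropped so the
#' path covers the navigation phase only.
#'
#' @param x A `trial_result` or a data.frame with `t_s`, `x_cm`, `y_cm`.
#' @param ... Unused.
#' @return A [tracked_path()].
#' @export
as_tracked_path <- function(x, ...) UseMethod("as_tracked_path")

#' @rdname as_tracked_path
#' @export
as_tracked_path.trial_result <- function(x, ...) {
  tr <- x$trajectory[x$trajectory$provenance != "baseline", , drop = FALSE]
  if (nrow(tr) == 0) tr <- x$trajectory[nrow(x$trajectory), , drop = FALSE]
  ld <- x$geometry$chassis_radius_cm
  tracked_path(tr$t_s, tr$x_cm, tr$y_cm,
               nose_x = tr$x_cm + ld * cos(tr$heading_rad),
               nose_y = tr$y_cm + ld * sin(tr$heading_rad))
}

#' @rdname as_tracked_path
#' @export
as_tracked_path.data.frame <- function(x, ...) {
  if (all(c("t_s", "body_x", "body_y") %in% names(x))) {
    tracked_path(x$t_s, x$body_x, x$body_y, x$nose_x, x$nose_y)
  } else if (all(c("t_s", "x_cm", "y_cm") %in% names(x))) {
    tracked_path(x$t_s, x$x_cm, x$y_cm)
  } else {
    stop("data.frame needs columns t_s, body_x, body_y (or t_s, x_cm, y_cm)",
         call. = FALSE)
  }
}

#' Read a tracking CSV
#'
#' Columns `t_s`, `body_x`, `body_y` and optionally `nose_x`, `nose_y`.
#'
#' @param path CSV file path.
#' @return A [tracked_path()].
#' @export
read_tracking_csv <- function(path) {
  as_tracked_path(utils::read.csv(path))
}

seg_lengths <- function(xs, ys) sqrt(diff(xs)^2 + diff(ys)^2)

#' Path length
#'
#' Sum of frame-to-frame segment lengths of the body track (cm).
#'
#' @param path A [tracked_path()].
#' @export
path_length <- function(path) {
  sum(seg_lengths(path$body_x, path$body_y))
}

#' Linearity score
#'
#' Ratio of the Euclidean distance between the start and end points of the
#' trajectory to the actual path length. 1 means a perfectly straight path.
#'
#' @param path A [tracked_path()] with at least 2 frames.
#' @return A value in `(0, 1]`.
#' @examples
#' p <- tracked_path(0:2, c(0, 3, 3), c(0, 0, 4))
#' path_linearity(p)  # 5 / 7
#' @export
path_linearity <- function(path) {
  if (nrow(path) < 2L) stop("need >= 2 frames", call. = FALSE)
  pl <- path_length(path)
  if (pl == 0) stop("degenerate path: zero path length", call. = FALSE)
  n <- nrow(path)
  sqrt((path$body_x[n] - path$body_x[1])^2 +
       (path$body_y[n] - path$body_y[1])^2) / pl
}

#' Total angle sum
#'
#' Sum of absolute frame-to-frame turning angles along the body track, in
#' degrees: the signed heading change between consecutive displacement
#' segments, accumulated as absolute values. Zero-length segments (frames
#' with no displacement) are skipped, since they carry no heading. A
#' full-body "casting" proxy.
#'
#' @param path A [tracked_path()] with at least 3 frames.
#' @return Total turning in degrees (0 for a straight path).
#' @export
total_angle_sum <- function(path) {
  dx <- diff(path$body_x)
  dy <- diff(path$body_y)
  keep <- dx != 0 | dy != 0
  if (sum(keep) < 2L) return(0)
  headings <- atan2(dy[keep], dx[keep])
  sum(abs(rad2deg(wrap_pi(diff(headings)))))
}

#' Wall-hugging (thigmotaxis) fraction
#'
#' Fraction of frames whose body point lies within `band_cm` of any arena
#' wall (default 5 cm), the standard thigmotaxis band.
#'
#' @param path A [tracked_path()].
#' @param arena An [arena_spec()].
#' @param band_cm Band width in cm.
#' @return A fraction in `[0, 1]`.
#' @export
wall_hugging_fraction <- function(path, arena, band_cm = 5) {
  d <- pmin(path$body_x, arena$length_cm - path$body_x,
            path$body_y, arena$width_cm - path$body_y)
  mean(d <= band_cm)
}

#' Nose/body path-length ratio
#'
#' Ratio of the path length traced by the nose point to that traced by the
#' body point; values above 1 indicate lateral head sweeps superimposed on
#' the body trajectory.
#'
#' @param path A [tracked_path()] carrying a nose track.
#' @return Ratio (> 0).
#' @export
nose_body_ratio <- function(path) {
  if (!has_nose(path)) stop("path has no nose track", call. = FALSE)
  bl <- path_length(path)
  if (bl == 0) stop("degenerate path: zero body path length", call. = FALSE)
  sum(seg_lengths(path$nose_x, path$nose_y)) / bl
}

#' Per-frame change in nose angle
#'
#' The nose angle is the bearing from the body point to the nose point; this
#' reports its absolute frame-to-frame change in degrees, plus the mean. A
#' head-sweep ("casting") proxy at the tracking frame rate. Frames where the
#' nose and body coincide carry no bearing and are skipped.
#'
#' @param path A [tracked_path()] carrying a nose track.
#' @return A list with `per_frame_deg` and `mean_deg`.
#' @export
delta_nose_angle <- function(path) {
  if (!has_nose(path)) stop("path has no nose track", call. = FALSE)
  dx <- path$nose_x - path$body_x
  dy <- path$nose_y - path$body_y
  ok <- dx != 0 | dy != 0
  if (sum(!ok) > 0) {
    message("delta_nose_angle: skipped ", sum(!ok),
            " frame(s) with coincident nose/body points")
  }
  bearing <- atan2(dy[ok], dx[ok])
  per <- abs(rad2deg(wrap_pi(diff(bearing))))
  list(per_frame_deg = per, mean_deg = mean(per))
}

#' Resample a path to a fixed frame count
#'
#' Linear interpolation in time to exactly `n_frames` equally spaced samples
#' spanning the original time range; the first and last points are preserved
#' exactly. Used to average trajectories of unequal duration (e.g. to 755 or
#' 675 frames).
#'
#' @param path A [tracked_path()] with at least 2 frames.
#' @param n_frames Target frame count (>= 2).
#' @return A [tracked_path()] with `n_frames` rows.
#' @export
resample_path <- function(path, n_frames) {
  if (nrow(path) < 2L || n_frames < 2L) {
    stop("need >= 2 input frames and n_frames >= 2", call. = FALSE)
  }
  tt <- seq(path$t_s[1], path$t_s[nrow(path)], length.out = n_frames)
  interp <- function(v) stats::approx(path$t_s, v, xout = tt, ties = "ordered",
                                      rule = 2)$y
  out <- tracked_path(tt, interp(path$body_x), interp(path$body_y),
                      if (has_nose(path)) interp(path$nose_x),
                      if (has_nose(path)) interp(path$nose_y))
  # endpoints exact by construction, guard against interpolation rounding
  out[c(1, n_frames), -1] <- path[c(1, nrow(path)),
                                  setdiff(names(path), "t_s")]
  out
}

#' Summarize trial metrics by condition
#'
#' Per-group sample size, percent success, and mean +/- SEM of each metric,
#' plus pairwise Welch two-sample comparisons with Bonferroni correction
#' across groups (mirroring the mean +/- SEM reporting style of behavioral
#' condition summaries). Empty groups are excluded with a warning.
#'
#' @param results A data.frame with one row per trial, a logical/0-1
#'   `success` column, grouping columns and numeric metric columns.
#' @param grouping Character vector of grouping column names.
#' @param metrics Character vector of numeric metric columns to summarize
#'   (default: all numeric columns not in `grouping`/`success`).
#' @return A list with `summary` (one row per group) and `comparisons`
#'   (pairwise Welch tests per metric, Bonferroni-adjusted).
#' @export
summarize_conditions <- function(results, grouping,
                                 metrics = NULL) {
  stopifnot(is.data.frame(results), all(grouping %in% names(results)))
  if (is.null(metrics)) {
    metrics <- setdiff(names(results)[vapply(results, is.numeric, TRUE)],
                       c(grouping, "success", "seed", "start_frame",
                         "replicate", "angle_deg"))
  }
  key <- interaction(results[grouping], drop = FALSE, sep = " / ")
  groups <- split(results, key)
  empty <- vapply(groups, nrow, 0L) == 0L
  if (any(empty)) {
    warning("excluded empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    row <- data.frame(group = g, n = nrow(df),
                      pct_success = if ("success" %in% names(df))
                        100 * mean(df$success) else NA_real_)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(df[[m]], na.rm = TRUE)
      row[[paste0(m, "_sem")]] <- sem(df[[m]][!is.na(df[[m]])])
    }
    row
  }))
  comparisons <- NULL
  gn <- names(groups)
  if (length(gn) >= 2L) {
    pairs <- utils::combn(gn, 2, simplify = FALSE)
    rows <- list()
    for (m in metrics) {
      for (pr in pairs) {
        a <- groups[[pr[1]]][[m]]; b <- groups[[pr[2]]][[m]]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, group_a = pr[1], group_b = pr[2],
          diff = mean(a) - mean(b), p_value = p)
      }
    }
    comparisons <- do.call(rbind, rows)
    comparisons$p_bonferroni <- pmin(1, comparisons$p_value * nrow(comparisons))
  }
  list(summary = summ, comparisons = comparisons)
}
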