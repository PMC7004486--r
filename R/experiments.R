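#' Sweep configuration
#'
#' Describes a batch experiment over start angles, mirroring the reference
#' design: start angles from 90 to 270 degrees at 3.6-degree increments (51
#' angles), 20 replicates per angle, one plume mode (static or dynamic), one
#' active source, one controller code and one sensor separation.
#'
#' @param code `"A"` or `"B"`.
#' @param sensor_sep_cm Sensor separation in cm (8 or 16 typical).
#' @param plume_mode `"static"` or `"dynamic"`.
#' @param source Port name or `(x, y)` position of the active source.
#' @param angles_deg Start angles in degrees (default `seq(90, 270, 3.6)`).
#' @param replicates Trials per angle (default 20). On a static plume the
#'   replicates are deterministic duplicates.
#' @param base_seed Base of the hierarchical per-trial seed derivation.
#' @param params A [navigator_params()]; its `code` is overridden by `code`.
#' @param geometry An [agent_geometry()]; its separation is overridden by
#'   `sensor_sep_cm`.
#' @param arena An [arena_spec()].
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(code = c("A", "B"), sensor_sep_cm = 8,
                         plume_mode = c("static", "dynamic"),
                         source = "center",
                         angles_deg = seq(90, 270, by = 3.6),
                         replicates = 20, base_seed = 1,
                         params = navigator_params(),
                         geometry = agent_geometry(),
                         arena = arena_spec()) {
  code <- match.arg(code)
  plume_mode <- match.arg(plume_mode)
  if (length(angles_deg) < 1L) stop("angle range is empty", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  params$code <- code
  geometry$sensor_sep_cm <- sensor_sep_cm
  structure(list(code = code, sensor_sep_cm = sensor_sep_cm,
                 plume_mode = plume_mode, source = source,
                 angles_deg = angles_deg, replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 params = params, geometry = geometry, arena = arena),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf(
    "<sweep_config> Code %s, ls=%g cm, %s plume, %d angles x %d reps\n",
    x$code, x$sensor_sep_cm, x$plume_mode, length(x$angles_deg),
    x$replicates))
  invisible(x)
}

# Deterministic per-trial seed: re-runnable in isolation, always < 2^31.
trial_seed <- function(base_seed, angle_idx, replicate) {
  (abs(base_seed) %% 21474L) * 100000L + angle_idx * 100L + replicate
}

#' Run a start-angle sweep
#'
#' Runs `length(angles_deg) * replicates` trials. Each trial's seed is
#' derived arithmetically from `(base_seed, angle index, replicate)` (see the
#' `seed` column of the output), so the full table is reproducible from
#' `base_seed` and any single trial can be re-run in isolation with
#' [run_trial()]. Static-plume trials ignore the seed (they are
#' deterministic).
#'
#' @param config A [sweep_config()].
#' @param plume The plume to navigate; for `plume_mode = "static"` pass a
#'   [static_plume()] (e.g. [time_average()] of the movie), otherwise a
#'   [dynamic_plume()].
#' @param progress Print a line per angle (default FALSE).
#' @return An object of class `sweep_result`: `trials` is a long-form
#'   data.frame (one row per angle x replicate with `success`,
#'   `time_to_target_s`, `linearity`, `angle_sum_deg`, `pathlength_cm`,
#'   `seed`, `start_frame`), `by_replicate` aggregates percent success and
#'   mean linearity per replicate across angles (the unit of analysis for
#'   condition comparisons), and `config` echoes the design.
#' @export
run_sweep <- function(config, plume, progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  if (config$plume_mode == "static" && !inherits(plume, "static_plume")) {
    stop("config$plume_mode is 'static' but `plume` is not a static_plume",
         call. = FALSE)
  }
  if (config$plume_mode == "dynamic" && !inherits(plume, "dynamic_plume")) {
    stop("config$plume_mode is 'dynamic' but `plume` is not a dynamic_plume",
         call. = FALSE)
  }
  rows <- vector("list", length(config$angles_deg) * config$replicates)
  n <- 0L
  for (ai in seq_along(config$angles_deg)) {
    ang <- config$angles_deg[ai]
    for (ri in seq_len(config$replicates)) {
      sd_i <- trial_seed(config$base_seed, ai, ri)
      trial <- run_trial(plume, params = config$params,
                         arena = config$arena, geometry = config$geometry,
                         start_angle_deg = ang, source = config$source,
                         seed = sd_i)
      tp <- as_tracked_path(trial)
      pl <- path_length(tp)
      n <- n + 1L
      rows[[n]] <- data.frame(
        angle_deg = ang, replicate = ri, seed = sd_i,
        start_frame = trial$start_frame, success = trial$success,
        time_to_target_s = trial$time_to_target_s,
        linearity = if (pl > 0) path_linearity(tp) else NA_real_,
        angle_sum_deg = total_angle_sum(tp), pathlength_cm = pl)
    }
    if (progress) {
      message(sprintf("angle %5.1f deg: %d/%d success", ang,
                      sum(vapply(rows[(n - config$replicates + 1L):n],
                                 function(r) r$success, TRUE)),
                      config$replicates))
    }
  }
  trials <- do.call(rbind, rows)
  by_rep <- do.call(rbind, lapply(split(trials, trials$replicate),
    function(df) data.frame(replicate = df$replicate[1],
                            pct_success = 100 * mean(df$success),
                            mean_linearity = mean(df$linearity, na.rm = TRUE))))
  structure(list(trials = trials, by_replicate = by_rep, config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  br <- x$by_replicate
  cat(sprintf(paste0("<sweep_result> Code %s, ls=%g cm, %s plume: ",
                     "%d trials\n  %% success %.1f +/- %.1f (SEM over %d ",
                     "replicates), linearity %.3f +/- %.3f\n"),
              x$config$code, x$config$sensor_sep_cm, x$config$plume_mode,
              nrow(x$trials), mean(br$pct_success), sem(br$pct_success),
              nrow(br), mean(br$mean_linearity), sem(br$mean_linearity)))
  invisible(x)
}

#' @export
summary.sweep_result <- function(object, ...) {
  tr <- object$trials
  by_angle <- do.call(rbind, lapply(split(tr, tr$angle_deg),
    function(df) data.frame(angle_deg = df$angle_deg[1],
                            pct_success = 100 * mean(df$success),
                            mean_linearity = mean(df$linearity, na.rm = TRUE))))
  rownames(by_angle) <- NULL
  list(by_angle = by_angle, by_replicate = object$by_replicate,
       overall = data.frame(
         pct_success = mean(object$by_replicate$pct_success),
         mean_linearity = mean(object$by_replicate$mean_linearity),
         n_trials = nrow(tr)))
}

#' @export
plot.sweep_result <- function(x, ...) {
  s <- summary(x)$by_angle
  graphics::plot(s$angle_deg, s$pct_success, type = "o", pch = 16,
                 xlab = "start angle (deg)", ylab = "% success",
                 ylim = c(0, 100), ...)
  invisible(x)
}

# Welch t-test that tolerates deterministic (zero-variance) groups.
welch_p <- function(a, b, alternative = "two.sided") {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    delta <- mean(a) - mean(b)
    return(switch(alternative,
                  two.sided = as.numeric(delta == 0),
                  greater = as.numeric(delta <= 0),
                  less = as.numeric(delta >= 0)))
  }
  stats::t.test(a, b, alternative = alternative)$p.value
}

#' Compare two sweep conditions
#'
#' Differences in mean percent success and mean linearity between two sweeps
#' on the same angle grid, with SEMs and Welch tests on the per-replicate
#' values (the unit the reference design reports: each replicate's percent
#' success over all start angles). Swapping the arguments flips the signs.
#'
#' @param a,b [run_sweep()] results sharing the same angle grid.
#' @param alternative Passed to the Welch test; `"greater"` tests
#'   `a > b` one-sided.
#' @return A data.frame with one row per metric: means, difference, SEM of
#'   the difference and p-value.
#' @export
compare_conditions <- function(a, b, alternative = "two.sided") {
  stopifnot(inherits(a, "sweep_result"), inherits(b, "sweep_result"))
  if (!isTRUE(all.equal(a$config$angles_deg, b$config$angles_deg))) {
    stop("sweeps were run on different angle grids", call. = FALSE)
  }
  sem2 <- function(u, v) {
    sqrt(stats::sd(u)^2 / length(u) + stats::sd(v)^2 / length(v))
  }
  one <- function(metric) {
    u <- a$by_replicate[[metric]]; v <- b$by_replicate[[metric]]
    data.frame(metric = metric, mean_a = mean(u), mean_b = mean(v),
               diff = mean(u) - mean(v), sem_diff = sem2(u, v),
               p_value = welch_p(u, v, alternative))
  }
  rbind(one("pct_success"), one("mean_linearity"))
}
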