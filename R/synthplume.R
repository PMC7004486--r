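#' Synthetic chaotic-plume parameters
#'
#' Parameters of the bundled Gaussian-puff plume generator, a stand-in for
#' measured PLIF concentration movies. Discrete puffs are released at the
#' source on the inlet wall, advected downstream at the mean flow speed,
#' spread by an effective diffusivity, and displaced laterally by a shared
#' Ornstein-Uhlenbeck meander process sampled at release (frozen-field
#' advection), which makes the instantaneous plume snake while its long-run
#' time average stays a smooth centered gradient.
#'
#' Defaults emulate the reference chamber: 5 cm/s flow, a 4-minute movie at
#' 15 fps on a 100 x 100 cm grid at 1 px/cm. The `complexity` preset mimics
#' removing the inlet flow-straightener: `"high"` triples the meander SD and
#' halves the puff rate, inflating the concentration SD (and SD/mean) at
#' downstream probes by the observed factor of roughly 2-4.
#'
#' @param source `(x, y)` source position on the inlet wall (`x = 0`).
#' @param advection_cm_s Mean flow speed (default 5 cm/s).
#' @param puff_rate_hz Puff release rate before the complexity preset.
#' @param puff_init_radius_cm Initial puff radius \eqn{\sigma_0} (cm).
#' @param puff_growth_cm2_s Effective diffusivity: puff variance grows as
#'   \eqn{\sigma^2(a) = \sigma_0^2 + g\,a} with age \eqn{a}.
#' @param meander_sd_cm Stationary SD of the lateral centerline offset before
#'   the complexity preset.
#' @param meander_timescale_s OU relaxation time of the meander.
#' @param duration_s Movie duration (default 240 s).
#' @param fps Frame rate (default 15).
#' @param px_per_cm Grid resolution (default 1).
#' @param complexity `"low"` or `"high"` preset.
#' @param seed Optional integer seed used by [make_dynamic()].
#' @return An object of class `synth_plume_params` with the preset already
#'   applied to `puff_rate_hz` and `meander_sd_cm`.
#' @export
synth_plume_params <- function(source = c(0, 50), advection_cm_s = 5,
                               puff_rate_hz = 5, puff_init_radius_cm = 3,
                               puff_growth_cm2_s = 5, meander_sd_cm = 5,
                               meander_timescale_s = 5, duration_s = 240,
                               fps = 15, px_per_cm = 1,
                               complexity = c("low", "high"), seed = NULL) {
  complexity <- match.arg(complexity)
  vals <- c(advection_cm_s, puff_rate_hz, puff_init_radius_cm,
            puff_growth_cm2_s, meander_sd_cm, meander_timescale_s,
            duration_s, fps, px_per_cm)
  stopifnot_finite(vals, "synth_plume_params")
  if (any(vals <= 0)) stop("all rates and scales must be > 0", call. = FALSE)
  if (duration_s * fps < 1) stop("duration_s * fps must be >= 1", call. = FALSE)
  if (complexity == "high") {
    meander_sd_cm <- 3 * meander_sd_cm
    puff_rate_hz <- 0.5 * puff_rate_hz
  }
  structure(list(source = as.numeric(source),
                 advection_cm_s = advection_cm_s,
                 puff_rate_hz = puff_rate_hz,
                 puff_init_radius_cm = puff_init_radius_cm,
                 puff_growth_cm2_s = puff_growth_cm2_s,
                 meander_sd_cm = meander_sd_cm,
                 meander_timescale_s = meander_timescale_s,
                 duration_s = duration_s, fps = fps, px_per_cm = px_per_cm,
                 complexity = complexity, seed = seed),
            class = "synth_plume_params")
}

#' @export
print.synth_plume_params <- function(x, ...) {
  cat(sprintf(paste0("<synth_plume_params> %s complexity: U=%g cm/s, ",
                     "%.2g puffs/s, meander sd %g cm, %g s @ %g fps\n"),
              x$complexity, x$advection_cm_s, x$puff_rate_hz,
              x$meander_sd_cm, x$duration_s, x$fps))
  invisible(x)
}

check_on_inlet <- function(params, arena) {
  s <- params$source
  if (s[1] != 0 || s[2] < 0 || s[2] > arena$width_cm) {
    stop("synthetic plume source must lie on the inlet wall (x = 0)",
         call. = FALSE)
  }
}

#' Analytic time-averaged synthetic plume
#'
#' Closed-form counterpart of the generator's long-run time average: a
#' Gaussian plume with downstream-widening cross-section,
#' \eqn{C(d, l) \propto (\sigma_0/\sigma(d)) \exp(-l^2 / (2\sigma(d)^2))}
#' with \eqn{\sigma(d) = \sigma_0 + s\,d}, where the spread rate \eqn{s} is
#' matched to the puff growth over one arena transit. Normalized so the
#' source pixel equals 1.
#'
#' @param params A [synth_plume_params()].
#' @param arena An [arena_spec()].
#' @return A [static_plume()].
#' @export
make_static <- function(params, arena) {
  stopifnot(inherits(params, "synth_plume_params"))
  check_on_inlet(params, arena)
  s0 <- params$puff_init_radius_cm
  transit <- arena$length_cm / params$advection_cm_s
  spread <- (sqrt(s0^2 + params$puff_growth_cm2_s * transit) - s0) /
    arena$length_cm
  nx <- round(arena$length_cm * params$px_per_cm)
  ny <- round(arena$width_cm * params$px_per_cm)
  xs <- (seq_len(nx) - 0.5) / params$px_per_cm
  ys <- (seq_len(ny) - 0.5) / params$px_per_cm
  sig <- s0 + spread * xs                     # d = downstream distance = x
  lat <- ys - params$source[2]
  grid <- (s0 / sig) * exp(-outer(1 / (2 * sig^2), lat^2))
  src_idx <- pixel_index(static_plume(grid, params$px_per_cm),
                         params$source + c(1e-9, 0))
  static_plume(grid / grid[src_idx[1], src_idx[2]], params$px_per_cm)
}

#' Generate a synthetic dynamic plume movie
#'
#' Renders the puff model frame by frame: puffs are released at fixed
#' intervals `1/puff_rate_hz` (starting one arena transit before frame 1 so
#' the plume is fully developed), each carrying a frozen lateral offset drawn
#' from a shared OU meander sampled at its release time. A puff of age
#' \eqn{a} sits at downstream distance \eqn{U a} with radius
#' \eqn{\sigma(a) = \sqrt{\sigma_0^2 + g a}} and peak amplitude
#' \eqn{\sigma_0^2/\sigma^2(a)} (2-D mass conservation). Frames are
#' max-normalized over the whole movie (not per frame) so temporal
#' fluctuations survive normalization.
#'
#' Uses R's RNG: `params$seed` is applied via [set.seed()] when present,
#' otherwise seed the session yourself for reproducibility.
#'
#' @inheritParams make_static
#' @return A [dynamic_plume()].
#' @export
make_dynamic <- function(params, arena) {
  stopifnot(inherits(params, "synth_plume_params"))
  check_on_inlet(params, arena)
  if (!is.null(params$seed)) set.seed(params$seed)

  U <- params$advection_cm_s
  s0 <- params$puff_init_radius_cm
  g <- params$puff_growth_cm2_s
  nx <- round(arena$length_cm * params$px_per_cm)
  ny <- round(arena$width_cm * params$px_per_cm)
  xs <- (seq_len(nx) - 0.5) / params$px_per_cm
  ys <- (seq_len(ny) - 0.5) / params$px_per_cm
  nt <- round(params$duration_s * params$fps)

  # age at which a puff has fully crossed the arena (center 3 sigma beyond)
  max_age <- stats::uniroot(
    function(a) U * a - 3 * sqrt(s0^2 + g * a) - arena$length_cm,
    c(arena$length_cm / U, 10 * arena$length_cm / U + 100))$root
  dt_rel <- 1 / params$puff_rate_hz
  t_rel <- seq(-max_age, params$duration_s, by = dt_rel)
  n_puff <- length(t_rel)

  # shared OU meander sampled at release times (exact AR(1) discretization)
  rho <- exp(-dt_rel / params$meander_timescale_s)
  innov <- stats::rnorm(n_puff, 0, params$meander_sd_cm * sqrt(1 - rho^2))
  offset <- numeric(n_puff)
  offset[1] <- stats::rnorm(1, 0, params$meander_sd_cm)
  for (p in seq_len(n_puff - 1L)) {
    offset[p + 1L] <- rho * offset[p] + innov[p + 1L]
  }
  yc_all <- params$source[2] + offset

  frames <- array(0, dim = c(nx, ny, nt))
  first_alive <- 1L
  for (k in seq_len(nt)) {
    t_k <- (k - 1L) / params$fps
    while (first_alive <= n_puff && t_k - t_rel[first_alive] > max_age) {
      first_alive <- first_alive + 1L
    }
    alive <- first_alive:n_puff
    alive <- alive[t_rel[alive] <= t_k]
    if (!length(alive)) next
    frame <- matrix(0, nx, ny)
    for (p in alive) {
      a <- t_k - t_rel[p]
      sig2 <- s0^2 + g * a
      sig <- sqrt(sig2)
      xc <- params$source[1] + U * a
      yc <- yc_all[p]
      i1 <- max(1L, floor((xc - 3 * sig) * params$px_per_cm) + 1L)
      i2 <- min(nx, ceiling((xc + 3 * sig) * params$px_per_cm))
      j1 <- max(1L, floor((yc - 3 * sig) * params$px_per_cm) + 1L)
      j2 <- min(ny, ceiling((yc + 3 * sig) * params$px_per_cm))
      if (i1 > i2 || j1 > j2) next
      gx <- exp(-(xs[i1:i2] - xc)^2 / (2 * sig2))
      gy <- exp(-(ys[j1:j2] - yc)^2 / (2 * sig2))
      frame[i1:i2, j1:j2] <- frame[i1:i2, j1:j2] +
        (s0^2 / sig2) * outer(gx, gy)
    }
    frames[, , k] <- frame
  }
  frames <- frames / max(frames)
  dynamic_plume(frames, fps = params$fps, px_per_cm = params$px_per_cm)
}
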