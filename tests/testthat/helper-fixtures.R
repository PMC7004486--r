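# Shared fixtures, built in code and memoised across test files. Simulated
# movies are shorter than the 240-s generator default to keep the suite fast;
# the trials loop them continuously, so trial length is unaffected.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# 40-s (600-frame) low-complexity synthetic movie on the full arena
acc_movie <- function() fixture("acc_movie", {
  make_dynamic(synth_plume_params(duration_s = 40, fps = 15, seed = 20260917),
               arena_spec())
})

acc_static <- function() fixture("acc_static", time_average(acc_movie()))

# Memoised 51-angle x 5-replicate sweeps on the shared movie
acc_sweep <- function(code, mode) {
  fixture(paste0("acc_sweep_", code, "_", mode), {
    cfg <- sweep_config(code, sensor_sep_cm = 8, plume_mode = mode,
                        replicates = 5, base_seed = 11)
    run_sweep(cfg, if (mode == "static") acc_static() else acc_movie())
  })
}

# Complexity-contrast and puff-rate movies (shared by property and
# acceptance tests)
cx_movie <- function(complexity) {
  fixture(paste0("cx_", complexity), {
    make_dynamic(synth_plume_params(duration_s = 60, fps = 15,
                                    complexity = complexity, seed = 55),
                 arena_spec())
  })
}

# Slow-growing puffs (growth 1 cm^2/s) keep the signal from saturating the
# intermittency threshold at every rate, so the rate ordering is informative.
rate_movie <- function(rate) {
  fixture(paste0("rate_", rate), {
    make_dynamic(synth_plume_params(puff_rate_hz = rate,
                                    puff_growth_cm2_s = 1, duration_s = 40,
                                    fps = 15, seed = 91), arena_spec())
  })
}

# Uniform fields for sensing/navigation contracts
uniform_static <- function(value = 0.5, n = 100) {
  static_plume(matrix(value, n, n))
}

uniform_dynamic <- function(value = 0.5, n = 20, n_frames = 30, fps = 15) {
  dynamic_plume(array(value, c(n, n, n_frames)), fps = fps,
                px_per_cm = n / 100)
}

zero_plume <- function(n = 100) static_plume(matrix(0, n, n))

# Deterministic pseudo-random walk path fixture
random_walk_path <- function(n = 50, seed = 1) {
  set.seed(seed)
  tracked_path(seq_len(n), cumsum(stats::rnorm(n)), cumsum(stats::rnorm(n)))
}
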