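#' @keywords internal
"_PACKAGE"

# Wrap an angle to [0, 2*pi).
wrap_2pi <- function(theta) {
  theta <- theta %% (2 * pi)
  # %% can return 2*pi for tiny negative inputs through rounding
  theta[theta >= 2 * pi] <- theta[theta >= 2 * pi] - 2 * pi
  theta
}

# Wrap an angle to (-pi, pi].
wrap_pi <- function(theta) {
  out <- wrap_2pi(theta)
  out[out > pi] <- out[out > pi] - 2 * pi
  out
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("invalid state: `", what, "` must be finite numeric", call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
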