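#' Flow-arena specification
#'
#' Describes the rectangular flow chamber in which trials run. The coordinate
#' convention is: `x` increases in the flow direction, with the inlet wall
#' (where the odor ports sit) at `x = 0` and the outlet wall at
#' `x = length_cm`; `y` is the flow-transverse coordinate in
#' `[0, width_cm]`. Angles follow the mathematical convention, so a heading of
#' 180 degrees faces the inlet wall (and hence the odor source).
#'
#' The default ports reproduce the three odor tubes of the physical chamber:
#' one on the midline and two 25 cm lateral to it. `"center"` refers to the
#' midline port, `"corner"` to a lateral port.
#'
#' @param width_cm Arena extent transverse to the flow (cm).
#' @param length_cm Arena extent in the flow direction (cm).
#' @param ports Named list of 2-column port positions `(x, y)` in cm on the
#'   inlet boundary. Must contain at least one port.
#' @return An object of class `arena_spec`.
#' @examples
#' arena <- arena_spec()
#' arena$ports$center
#' @export
arena_spec <- function(width_cm = 100, length_cm = 100,
                       ports = list(corner = c(0, 25),
                                    center = c(0, 50),
                                    port3  = c(0, 75))) {
  stopifnot_finite(width_cm, "width_cm")
  stopifnot_finite(length_cm, "length_cm")
  if (width_cm <= 0 || length_cm <= 0) {
    stop("arena dimensions must be positive", call. = FALSE)
  }
  if (!is.list(ports) || length(ports) < 1L) {
    stop("`ports` must be a non-empty named list of (x, y) positions",
         call. = FALSE)
  }
  for (nm in names(ports)) {
    p <- ports[[nm]]
    stopifnot_finite(p, paste0("ports$", nm))
    if (length(p) != 2L ||
        p[1] < 0 || p[1] > length_cm || p[2] < 0 || p[2] > width_cm) {
      stop("port `", nm, "` must be a 2-vector on or inside the arena",
           call. = FALSE)
    }
  }
  structure(list(width_cm = width_cm, length_cm = length_cm, ports = ports),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g cm (flow) x %g cm (transverse), %d port(s): %s\n",
              x$length_cm, x$width_cm, length(x$ports),
              paste(names(x$ports), collapse = ", ")))
  invisible(x)
}

#' Resolve a source position inside an arena
#'
#' @param arena An [arena_spec()].
#' @param source Either a port name (e.g. `"center"`) or a numeric `(x, y)`
#'   position in cm.
#' @return Numeric length-2 position.
#' @export
resolve_source <- function(arena, source = "center") {
  if (is.character(source)) {
    if (!source %in% names(arena$ports)) {
      stop("unknown port `", source, "`; available: ",
           paste(names(arena$ports), collapse = ", "), call. = FALSE)
    }
    return(as.numeric(arena$ports[[source]]))
  }
  stopifnot_finite(source, "source")
  if (length(source) != 2L) stop("`source` must be a port name or (x, y)",
                                 call. = FALSE)
  as.numeric(source)
}

# Distance from a point to the nearest arena wall.
wall_distance <- function(x, y, arena) {
  min(x, arena$length_cm - x, y, arena$width_cm - y)
}
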