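# Natural-cubic-spline interpolation from grid nodes to a refined grid is
# linear in the node values, so it can be precomputed as a matrix operator
# (one column per node, obtained by splining the unit basis vectors). The
# tensor product of the two 1-D operators gives the bicubic surface.
.spline_operator <- function(nodes, fine) {
  W <- vapply(seq_along(nodes), function(j) {
    e <- numeric(length(nodes))
    e[j] <- 1
    spline(nodes, e, xout = fine, method = "natural")$y
  }, numeric(length(fine)))
  W
}

.surface_grids <- function(arena, subdivisions, extend_to_walls = FALSE) {
  if (extend_to_walls) {
    # same cell step, but the evaluation grid runs wall to wall (the spline
    # extrapolates linearly past the outermost electrodes, so the centre of
    # gravity can follow a fish inside the electrode-free margin)
    list(
      x = seq(0, arena$width_x, by = arena$pitch_x / subdivisions),
      y = seq(0, arena$width_y, by = arena$pitch_y / subdivisions)
    )
  } else {
    list(
      x = seq(arena$grid_x[1], arena$grid_x[arena$nx],
        length.out = (arena$nx - 1) * subdivisions + 1
      ),
      y = seq(arena$grid_y[1], arena$grid_y[arena$ny],
        length.out = (arena$ny - 1) * subdivisions + 1
      )
    )
  }
}

# cache the two operators per (arena, subdivisions) in an environment
.surface_cache <- new.env(parent = emptyenv())
.surface_ops <- function(arena, subdivisions, extend_to_walls = FALSE) {
  key <- paste(arena$nx, arena$ny, round(arena$width_x, 6),
    round(arena$width_y, 6), subdivisions, extend_to_walls,
    sep = "_"
  )
  if (!is.null(.surface_cache[[key]])) return(.surface_cache[[key]])
  g <- .surface_grids(arena, subdivisions, extend_to_walls)
  ops <- list(
    Wx = .spline_operator(arena$grid_x, g$x),
    Wy = .spline_operator(arena$grid_y, g$y),
    grid = g
  )
  .surface_cache[[key]] <- ops
  ops
}

#' Interpolate the peak-power map onto a refined grid
#'
#' Bicubic (tensor-product natural cubic) spline evaluation of per-electrode
#' peak power on a grid that subdivides the distance between adjacent
#' electrodes into `subdivisions` equal parts along each axis. Negative
#' interpolants (spline overshoot) are clamped to zero. Requires the
#' electrodes to lie on a regular grid.
#'
#' @param power per-electrode peak power: either a length-L vector in
#'   electrode order or an `nx` x `ny` matrix.
#' @param arena the [arena_geometry()] the electrodes live on.
#' @param subdivisions refinement factor (default 5).
#' @param extend_to_walls evaluate the (extrapolated) surface over the full
#'   arena instead of only the electrode hull; used by the tracker so the
#'   estimate can follow a fish into the electrode-free margin.
#' @return A `peak_surface` list: `x`, `y` (refined coordinates, mm) and
#'   `power` (length(x) x length(y) matrix).
#' @export
interpolate_peak_surface <- function(power, arena = arena_geometry(),
                                     subdivisions = 5,
                                     extend_to_walls = FALSE) {
  if (is.null(arena$nx) || is.null(arena$ny)) {
    stop("unsupported electrode layout: regular grid required")
  }
  if (is.matrix(power)) {
    if (!all(dim(power) == c(arena$nx, arena$ny))) {
      stop("power matrix does not match the electrode grid")
    }
    P <- power
  } else {
    if (length(power) != n_electrodes(arena)) {
      stop("power vector length does not match the electrode count")
    }
    P <- matrix(power, arena$nx, arena$ny) # column-major matches arena_geometry
  }
  ops <- .surface_ops(arena, subdivisions, extend_to_walls)
  dense <- ops$Wx %*% P %*% t(ops$Wy)
  dense[dense < 0] <- 0
  structure(list(x = ops$grid$x, y = ops$grid$y, power = dense),
    class = "peak_surface"
  )
}

#' Centre of gravity of a power surface
#'
#' Power-weighted mean of the grid coordinates. An all-zero surface is
#' degenerate: the previous estimate is returned if available, otherwise the
#' arena centre, and the result is flagged.
#'
#' @param surface a `peak_surface`.
#' @param previous optional previous position estimate `c(x, y)`.
#' @param centre fallback position when there is no previous estimate.
#' @return Numeric `c(x, y)` in mm with attribute `degenerate`.
#' @export
centre_of_gravity <- function(surface, previous = NULL, centre = NULL) {
  w <- surface$power
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) {
    fallback <- previous %||% centre %||%
      c(mean(range(surface$x)), mean(range(surface$y)))
    return(structure(as.numeric(fallback), degenerate = TRUE))
  }
  cx <- sum(rowSums(w) * surface$x) / tot
  cy <- sum(colSums(w) * surface$y) / tot
  structure(c(cx, cy), degenerate = FALSE)
}

#' Raw position track from peak maps
#'
#' For each tick, interpolates the peak-power map onto the refined grid,
#' subtracts the background level (the median refined power, which removes
#' the spatially flat contribution of measurement noise) and takes the
#' centre of gravity. Degenerate ticks (no power anywhere) hold the last
#' estimate and are flagged.
#'
#' @param maps a `peak_maps` object.
#' @param subdivisions spline refinement factor.
#' @param background `"median"` (default) or `"none"`.
#' @param threshold relative support threshold: refined-grid cells below
#'   `threshold * max(power)` are zeroed before the centre of gravity,
#'   localising the estimate around the dominant blob and limiting the
#'   inward bias where the power distribution is truncated by a wall.
#' @return Data frame `t`, `x_raw`, `y_raw`, `degenerate`.
#' @export
track_positions <- function(maps, subdivisions = 5,
                            background = c("median", "none"),
                            threshold = 0.2) {
  background <- match.arg(background)
  nt <- length(maps$t)
  xs <- numeric(nt)
  ys <- numeric(nt)
  degen <- logical(nt)
  prev <- NULL
  for (k in seq_len(nt)) {
    surf <- interpolate_peak_surface(maps$power[k, ], maps$arena, subdivisions,
                                     extend_to_walls = TRUE)
    if (background == "median") {
      surf$power <- pmax(surf$power - median(surf$power), 0)
    }
    if (threshold > 0) {
      surf$power[surf$power < threshold * max(surf$power)] <- 0
    }
    cg <- centre_of_gravity(surf, previous = prev,
      centre = c(maps$arena$width_x / 2, maps$arena$width_y / 2)
    )
    degen[k] <- attr(cg, "degenerate")
    xs[k] <- cg[1]
    ys[k] <- cg[2]
    if (!degen[k]) prev <- c(xs[k], ys[k])
  }
  data.frame(t = maps$t, x_raw = xs, y_raw = ys, degenerate = degen)
}

#' Smooth a raw centre-of-gravity track
#'
#' Zero-phase low-pass filtering of the raw centre-of-gravity coordinates;
#' the result defines the estimated fish position. Smoothed positions are
#' clipped to the arena bounding box.
#'
#' @param raw data frame from [track_positions()] (columns `t`, `x_raw`,
#'   `y_raw`, optionally `degenerate`).
#' @param f_cut1 low-pass cutoff, Hz (must be below half the tick rate).
#' @param order Butterworth order.
#' @param arena arena used for clipping (optional).
#' @return A `position_track` data frame: `t`, `x_raw`, `y_raw`, `x`, `y`,
#'   `degenerate`.
#' @export
smooth_track <- function(raw, f_cut1 = 1, order = 4, arena = NULL) {
  if (nrow(raw) < 3) stop("need at least 3 ticks")
  fm <- 1 / median(diff(raw$t))
  if (f_cut1 >= fm / 2) stop("f_cut1 must be below half the tick rate")
  bf <- signal::butter(order, f_cut1 / (fm / 2), type = "low")
  x <- zerophase_filter(bf, raw$x_raw)
  y <- zerophase_filter(bf, raw$y_raw)
  if (!is.null(arena)) {
    x <- pmin(pmax(x, 0), arena$width_x)
    y <- pmin(pmax(y, 0), arena$width_y)
  }
  out <- data.frame(
    t = raw$t, x_raw = raw$x_raw, y_raw = raw$y_raw,
    x = x, y = y,
    degenerate = raw$degenerate %||% rep(FALSE, nrow(raw))
  )
  class(out) <- c("position_track", "data.frame")
  out
}

#' End-to-end position estimation from a raw recording
#'
#' Convenience chain: band-pass extraction, peak maps, centre-of-gravity
#' tracking, smoothing.
#'
#' @param rec an `electrode_recording` (raw).
#' @param spec ventilatory band-pass specification.
#' @param ... passed to [compute_peak_maps()].
#' @param f_cut1,order smoothing parameters, see [smooth_track()].
#' @param subdivisions spline refinement factor.
#' @return List with `track` (a `position_track`) and `maps` (`peak_maps`).
#' @export
estimate_track <- function(rec, spec = filter_spec(), subdivisions = 5,
                           f_cut1 = 1, order = 4, ...) {
  filt <- bandpass_extract(rec, spec)
  maps <- compute_peak_maps(filt, ...)
  raw <- track_positions(maps, subdivisions = subdivisions)
  list(track = smooth_track(raw, f_cut1 = f_cut1, order = order,
                            arena = rec$arena), maps = maps)
}
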