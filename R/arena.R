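#' Arena and electrode-array geometry
#'
#' Describes the measurement aquarium: a rectangular arena with a uniform
#' grid of electrodes fixed to the bottom. The default mirrors the study
#' system: a 210 x 140 mm arena with 126 electrodes on a 14 x 9 grid
#' (cell-centred, pitch 15 mm along x and about 15.6 mm along y).
#'
#' @param width_x,width_y arena dimensions in mm.
#' @param nx,ny number of electrode columns (along x) and rows (along y).
#' @return An object of class `arena_geometry`: a list with the arena
#'   dimensions, the electrode coordinate matrix `electrode_xy` (L x 2, mm),
#'   the grid shape and the electrode pitch in mm.
#' @examples
#' a <- arena_geometry()
#' nrow(a$electrode_xy) # 126
#' @export
arena_geometry <- function(width_x = 210, width_y = 140, nx = 14, ny = 9) {
  stopifnot(width_x > 0, width_y > 0, nx >= 2, ny >= 2)
  pitch_x <- width_x / nx
  pitch_y <- width_y / ny
  ex <- (seq_len(nx) - 0.5) * pitch_x
  ey <- (seq_len(ny) - 0.5) * pitch_y
  xy <- cbind(x = rep(ex, times = ny), y = rep(ey, each = nx))
  if (any(xy[, 1] < 0 | xy[, 1] > width_x | xy[, 2] < 0 | xy[, 2] > width_y)) {
    stop("electrode positions fall outside the arena")
  }
  structure(
    list(
      width_x = width_x, width_y = width_y,
      nx = nx, ny = ny,
      pitch_x = pitch_x, pitch_y = pitch_y,
      pitch = (pitch_x + pitch_y) / 2,
      grid_x = ex, grid_y = ey,
      electrode_xy = xy
    ),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf(
    "<arena_geometry> %g x %g mm, %d electrodes (%d x %d grid, pitch %.2f/%.2f mm)\n",
    x$width_x, x$width_y, nrow(x$electrode_xy), x$nx, x$ny, x$pitch_x, x$pitch_y
  ))
  invisible(x)
}

n_electrodes <- function(arena) nrow(arena$electrode_xy)

same_arena <- function(a, b) {
  isTRUE(all.equal(a$width_x, b$width_x)) &&
    isTRUE(all.equal(a$width_y, b$width_y)) &&
    identical(dim(a$electrode_xy), dim(b$electrode_xy)) &&
    isTRUE(all.equal(a$electrode_xy, b$electrode_xy))
}
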