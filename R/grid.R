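#' Display-board grid specification
#'
#' Describes the raster board on which dot-boundary stimuli are shown: a
#' `rows` x `cols` array of addressable dot positions. The defaults emulate
#' a 64 x 64 LED board whose dots are 4.9 arcmin wide and 9.2 arcmin apart
#' (center to center).
#'
#' Coordinates throughout the package are 0-based `(row, col)` pairs in
#' row-major order with row 0 at the top of the board; angles are measured
#' in degrees counterclockwise from the positive column axis.
#'
#' @param rows,cols Number of dot rows/columns; both must be at least 8.
#' @param dot_pitch Center-to-center dot spacing, in minutes of arc.
#' @param dot_diameter Dot diameter, in minutes of arc; must be smaller than
#'   `dot_pitch` so that neighboring dots do not touch.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec()
#' grid_spec(rows = 32, cols = 32)
#' @export
grid_spec <- function(rows = 64L, cols = 64L, dot_pitch = 9.2, dot_diameter = 4.9) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 8L || cols < 8L)
    stop("grid must have at least 8 rows and 8 columns")
  if (!is.finite(dot_pitch) || !is.finite(dot_diameter) ||
      dot_pitch <= 0 || dot_diameter <= 0)
    stop("dot_pitch and dot_diameter must be positive")
  if (dot_diameter >= dot_pitch)
    stop("dot_diameter must be smaller than dot_pitch")
  structure(
    list(rows = rows, cols = cols,
         dot_pitch = dot_pitch, dot_diameter = dot_diameter),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d board, pitch %.1f arcmin, dot %.1f arcmin\n",
              x$rows, x$cols, x$dot_pitch, x$dot_diameter))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) sprintf("%dx%d", x$rows, x$cols)
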