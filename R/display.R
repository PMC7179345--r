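identity_transform <- function() list(dx = 0, dy = 0, rotation = 0, scale = 1)

new_sampled_display <- function(shape_id, grid, dots, density, sampling_mode,
                                transform = identity_transform(),
                                partial = list(kind = "full")) {
  dots <- as_coord_matrix(dots)
  if (nrow(dots) == 0L) stop("display must contain at least one dot")
  if (!all(coords_on_grid(dots, grid))) stop("display dots fall outside the grid")
  if (anyDuplicated(paste(dots[, 1L], dots[, 2L]))) stop("display contains duplicate dots")
  structure(
    list(shape_id = shape_id, grid = grid, dots = dots,
         density = density, sampling_mode = sampling_mode,
         transform = transform, partial = partial),
    class = "sampled_display"
  )
}

#' @export
print.sampled_display <- function(x, ...) {
  cat(sprintf("<sampled_display> '%s': %d dots (density %.0f%%, %s sampling, %s)\n",
              x$shape_id, nrow(x$dots), 100 * x$density, x$sampling_mode,
              x$partial$kind))
  tr <- x$transform
  if (tr$dx != 0 || tr$dy != 0 || tr$rotation != 0 || tr$scale != 1)
    cat(sprintf("  transform: dx=%g dy=%g rotation=%g deg scale=%g\n",
                tr$dx, tr$dy, tr$rotation, tr$scale))
  invisible(x)
}

#' @export
plot.sampled_display <- function(x, ...) {
  plot_dots(x$dots, x$grid,
            main = sprintf("%s (%.0f%%)", x$shape_id, 100 * x$density), ...)
}

# shared base-graphics dot plotter (row 0 drawn at the top)
plot_dots <- function(dots, grid, main = "", ...) {
  graphics::plot(dots[, 2L], grid$rows - 1L - dots[, 1L],
                 xlim = c(0, grid$cols - 1L), ylim = c(0, grid$rows - 1L),
                 asp = 1, pch = 16, cex = 0.6, xlab = "col", ylab = "row (top = max)",
                 main = main, ...)
}

#' Full-density display of a shape
#'
#' Convenience wrapper: all boundary dots, in loop order.
#'
#' @param shape A [dot_shape()].
#' @return A `sampled_display` at density 1.
#' @export
full_display <- function(shape) {
  new_sampled_display(shape$shape_id, shape$grid, shape$boundary,
                      density = 1, sampling_mode = "even")
}

# even selection of m out of n loop positions with a given starting phase;
# gaps differ by at most one position
even_loop_indices <- function(n, m, phase) {
  ((phase + floor((0:(m - 1L)) * n / m)) %% n) + 1L
}

#' Sample a lower-density display from a boundary
#'
#' Lights `max(1, round(density * N))` of the `N` boundary dots. `"even"`
#' mode spaces the selected dots as evenly along the loop as integer
#' arithmetic allows, with a seed-determined starting phase (this is the
#' default stimulus style: visually uniform). `"random"` mode draws a
#' uniform sample without replacement. `density = 1` returns every dot in
#' loop order, unchanged.
#'
#' @param shape A [dot_shape()].
#' @param density Fraction of boundary dots to light, in `(0, 1]`.
#' @param mode `"even"` or `"random"`.
#' @param seed Integer seed (starting phase / random draw).
#' @return A `sampled_display`.
#' @examples
#' shp <- generate_inventory(1, seed = 1)[[1]]
#' sample_density(shp, 0.12, seed = 2)
#' @export
sample_density <- function(shape, density, mode = c("even", "random"), seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density <= 0 || density > 1)
    stop("density must lie in (0, 1]")
  b <- shape$boundary
  n <- nrow(b)
  if (density == 1) {
    return(new_sampled_display(shape$shape_id, shape$grid, b,
                               density = 1, sampling_mode = mode))
  }
  m <- max(1L, as.integer(round(density * n)))
  idx <- if (mode == "even") {
    phase <- with_seed(seed, sample.int(n, 1L)) - 1L
    even_loop_indices(n, m, phase)
  } else {
    sort(with_seed(seed, sample.int(n, m)))
  }
  new_sampled_display(shape$shape_id, shape$grid, b[idx, , drop = FALSE],
                      density = density, sampling_mode = mode)
}

#' Translate, rotate and scale a display
#'
#' Rotation (degrees counterclockwise, seen on the board) and scaling are
#' applied about the dot-set centroid in continuous coordinates, then the
#' translation `(dx, dy)` (columns right, rows down, in grid steps), then
#' each dot is rounded to the nearest grid cell. Dots that land on the same
#' cell are collapsed to one, so the returned dot count can fall below the
#' nominal count; the transform record is stored on the result.
#'
#' @param display A `sampled_display`.
#' @param dx,dy Translation in grid steps (columns, rows).
#' @param rotation Rotation in degrees, counterclockwise about the centroid.
#' @param scale Positive scale factor about the centroid.
#' @return A transformed `sampled_display`.
#' @examples
#' shp <- generate_inventory(1, seed = 1)[[1]]
#' apply_transform(full_display(shp), dx = 3, dy = -2)
#' @export
apply_transform <- function(display, dx = 0, dy = 0, rotation = 0, scale = 1) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  d <- display$dots
  cen <- colMeans(d)
  # continuous coordinates with y up so that positive rotation is
  # counterclockwise as seen on the board (row 0 at top)
  xr <- d[, 2L] - cen[2L]
  yr <- -(d[, 1L] - cen[1L])
  a <- rotation * pi / 180
  x2 <- scale * (cos(a) * xr - sin(a) * yr)
  y2 <- scale * (sin(a) * xr + cos(a) * yr)
  newc <- round(cen[2L] + x2 + dx)
  newr <- round(cen[1L] - y2 + dy)
  out <- cbind(row = as.integer(newr), col = as.integer(newc))
  ok <- coords_on_grid(out, display$grid)
  if (!all(ok)) {
    bad <- out[!ok, , drop = FALSE]
    stop(sprintf(
      "transform pushes %d dot(s) off the %s grid: %s",
      nrow(bad), format(display$grid),
      paste(sprintf("(%d,%d)", bad[, 1L], bad[, 2L]), collapse = " ")))
  }
  out <- dedupe_coords(out)
  new_sampled_display(display$shape_id, display$grid, out,
                      density = display$density,
                      sampling_mode = display$sampling_mode,
                      transform = list(dx = dx, dy = dy,
                                       rotation = rotation, scale = scale),
                      partial = display$partial)
}

#' Partial-boundary displays: half-perimeter and opposite-quarters
#'
#' `kind = "half"` keeps one contiguous arc of `round(N/2)` consecutive
#' boundary dots, starting at the boundary dot whose angle about the
#' full-boundary centroid is nearest `angle`. `kind = "opposite_quarters"`
#' keeps two contiguous arcs of `round(N/4)` dots whose starting indices sit
#' half the perimeter apart, i.e. on opposite sides of the shape. Density
#' sampling (even spacing) is then applied within the kept arcs. The
#' half-perimeter condition displaces the displayed centroid away from the
#' full-boundary centroid; opposite quarters nearly preserve it — the
#' geometric contrast probed by [centroid_displacement()].
#'
#' @param shape A [dot_shape()].
#' @param kind `"half"` or `"opposite_quarters"`.
#' @param angle Bisection / anchor angle in degrees (counterclockwise from
#'   the positive column axis, about the full-boundary centroid).
#' @param density Fraction of the kept dots to light, in `(0, 1]`.
#' @param seed Integer seed for the within-arc sampling phase.
#' @return A `sampled_display` whose `partial` field records the condition.
#' @examples
#' shp <- generate_inventory(1, seed = 1)[[1]]
#' make_partial(shp, "half", angle = 90, density = 0.25, seed = 3)
#' @export
make_partial <- function(shape, kind = c("half", "opposite_quarters"),
                         angle = 0, density = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  b <- shape$boundary
  n <- nrow(b)
  cen <- colMeans(b)
  ang <- coord_angle_deg(b, cen)
  start <- which.min(angle_diff_deg(ang, angle))
  arc_starts <- if (kind == "half") start
    else c(start, ((start - 1L + as.integer(round(n / 2))) %% n) + 1L)
  arc_len <- if (kind == "half") as.integer(round(n / 2)) else as.integer(round(n / 4))
  if (arc_len < 1L) stop("kept arc would be empty")
  keep <- lapply(arc_starts, function(s) ((s - 1L + 0:(arc_len - 1L)) %% n) + 1L)
  # density sampling within each kept arc (even spacing, seeded phase)
  kept <- with_seed(seed, {
    unlist(lapply(keep, function(idx) {
      m <- max(1L, as.integer(round(density * length(idx))))
      if (m >= length(idx)) return(idx)
      gap <- length(idx) / m
      phase <- stats::runif(1, 0, gap)
      idx[pmin(length(idx), floor(phase + (0:(m - 1L)) * gap) + 1L)]
    }))
  })
  partial <- if (kind == "half") list(kind = "half", bisection_angle = angle)
    else list(kind = "opposite_quarters", anchor_angle = angle)
  new_sampled_display(shape$shape_id, shape$grid,
                      b[kept, , drop = FALSE],
                      density = density, sampling_mode = "even",
                      partial = partial)
}

#' Minimum pairwise dot separation of a display, in arc degrees
#'
#' Queryable spacing property of a display: the smallest center-to-center
#' distance between any two lit dots, converted from grid steps to degrees
#' of visual angle via the grid's dot pitch.
#'
#' @param display A `sampled_display`.
#' @return Minimum pairwise separation in degrees of arc (Inf for a single
#'   dot).
#' @export
min_dot_separation_deg <- function(display) {
  d <- display$dots
  if (nrow(d) < 2L) return(Inf)
  min(stats::dist(d)) * display$grid$dot_pitch / 60
}
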