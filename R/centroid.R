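#' Centroid of a display
#'
#' Unweighted arithmetic mean of the lit dot coordinates, in continuous
#' grid units.
#'
#' @param display A `sampled_display`, `dot_shape`, or 2-column `(row, col)`
#'   coordinate matrix.
#' @return Numeric `(row, col)` pair.
#' @export
centroid <- function(display) {
  d <- display_dots(display)
  if (nrow(d) == 0L) stop("cannot take the centroid of an empty display")
  cen <- colMeans(d)
  names(cen) <- c("row", "col")
  cen
}

display_dots <- function(x) {
  if (inherits(x, "sampled_display")) x$dots
  else if (inherits(x, "dot_shape")) x$boundary
  else as_coord_matrix(x)
}

#' Centroid-distance signature of a display
#'
#' The centroid-based shape summary: the normalized distribution of
#' Euclidean distances from each lit dot to the dot-set centroid. Because
#' only distances to the centroid enter (the angle at which a dot lies is
#' deliberately ignored), the signature is exactly translation invariant
#' and rotation invariant up to grid re-quantization. With
#' `scale_normalize = TRUE` each distance is divided by the mean distance
#' and histogrammed over `[0, 3]` mean-radius units (values above 3 fall in
#' the top bin), making the summary size invariant as well; otherwise raw
#' distances are histogrammed over `[0, grid diagonal]`.
#'
#' @param display A `sampled_display` (or `dot_shape`) with at least two
#'   distinct dots.
#' @param n_bins Number of histogram bins (at least 2; default 16).
#' @param scale_normalize Divide distances by their mean before binning?
#' @return An object of class `centroid_signature` with fields `shape_id`,
#'   `centroid`, `mean_radius` (grid steps), and `bins` (weights summing
#'   to 1).
#' @examples
#' shp <- generate_inventory(1, seed = 1)[[1]]
#' sig <- distance_signature(full_display(shp))
#' sum(sig$bins)
#' @export
distance_signature <- function(display, n_bins = 16L, scale_normalize = TRUE) {
  if (n_bins < 2L) stop("n_bins must be at least 2")
  d <- dedupe_coords(display_dots(display))
  if (nrow(d) < 2L) stop("distance signature needs at least 2 distinct dots")
  cen <- colMeans(d)
  dist <- sqrt((d[, 1L] - cen[1L])^2 + (d[, 2L] - cen[2L])^2)
  mr <- mean(dist)
  if (scale_normalize) {
    v <- dist / mr
    top <- 3
  } else {
    v <- dist
    g <- if (inherits(display, "sampled_display") || inherits(display, "dot_shape"))
      display$grid else grid_spec()
    top <- sqrt((g$rows - 1)^2 + (g$cols - 1)^2)
  }
  width <- top / n_bins
  bin <- pmin(n_bins, floor(v / width) + 1L)  # values above `top` clamp to top bin
  counts <- tabulate(bin, nbins = n_bins)
  sid <- if (is.list(display) && !is.null(display$shape_id)) display$shape_id else NA_character_
  structure(
    list(shape_id = sid,
         centroid = c(row = unname(cen[1L]), col = unname(cen[2L])),
         mean_radius = mr,
         bins = counts / sum(counts),
         n_bins = as.integer(n_bins),
         scale_normalize = scale_normalize),
    class = "centroid_signature"
  )
}

#' @export
print.centroid_signature <- function(x, ...) {
  cat(sprintf("<centroid_signature> '%s': %d bins (%s), mean radius %.2f steps\n",
              x$shape_id, x$n_bins,
              if (x$scale_normalize) "scale-normalized" else "raw distances",
              x$mean_radius))
  invisible(x)
}

#' @export
plot.centroid_signature <- function(x, ...) {
  graphics::barplot(x$bins, names.arg = seq_along(x$bins) - 1L,
                    xlab = "distance bin", ylab = "weight",
                    main = x$shape_id, ...)
}

#' Sum-of-squared-differences between two centroid signatures
#'
#' The same comparison form used for scan histograms: \eqn{\sum_i (a_i - b_i)^2}.
#' Symmetric, non-negative, and zero exactly when the bins are identical.
#'
#' @param a,b `centroid_signature` objects with equal bin counts.
#' @return Non-negative similarity value (0 = identical).
#' @export
signature_similarity <- function(a, b) {
  if (length(a$bins) != length(b$bins))
    stop("signatures have different bin counts")
  sum_sq_diff(a$bins, b$bins)
}

#' Rank library shapes by centroid-signature similarity to a query display
#'
#' Encodes the query with [distance_signature()] and returns the library
#' sorted by ascending sum-of-squared-differences. Ties are broken by
#' library (shape id) order and flagged in the `ties` attribute.
#'
#' @param query A `sampled_display`.
#' @param library A list of `centroid_signature` objects.
#' @param n_bins,scale_normalize Encoding parameters; must match the
#'   library encoding.
#' @return A data frame with columns `shape_id` and `similarity`, sorted
#'   ascending; attribute `ties` is TRUE if the best similarity is shared.
#' @export
recognize <- function(query, library, n_bins = 16L, scale_normalize = TRUE) {
  if (length(library) == 0L) stop("library must be non-empty")
  q <- distance_signature(query, n_bins = n_bins, scale_normalize = scale_normalize)
  sims <- vapply(library, function(s) signature_similarity(q, s), numeric(1L))
  ids <- vapply(library, function(s) s$shape_id, character(1L))
  ord <- order(sims, seq_along(sims))
  out <- data.frame(shape_id = ids[ord], similarity = sims[ord],
                    stringsAsFactors = FALSE)
  attr(out, "ties") <- sum(sims == min(sims)) > 1L
  out
}

#' Centroid displacement of a partial display
#'
#' Euclidean distance (grid steps) between the full-boundary centroid of a
#' shape and the centroid of a partial display derived from it. Half-
#' perimeter displays of a ring of radius r displace the centroid by about
#' 2r/pi; opposite-quarters displays nearly preserve it — the geometric
#' contrast between the two partial-display conditions.
#'
#' @param shape The originating [dot_shape()].
#' @param partial_display A `sampled_display` derived from `shape`.
#' @return Non-negative displacement in grid steps.
#' @examples
#' shp <- generate_inventory(1, seed = 1, amplitude = 0)[[1]]
#' centroid_displacement(shp, make_partial(shp, "half", angle = 0))
#' @export
centroid_displacement <- function(shape, partial_display) {
  full <- centroid(shape)
  part <- centroid(partial_display)
  sqrt(sum((full - part)^2))
}
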