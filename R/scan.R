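#' Row and column projection counts of a display
#'
#' Counts the lit dots in each row and in each column of the display board.
#' On the default 64 x 64 board the concatenation (rows first, then
#' columns) is a single 128-bin histogram — the raw scan encoding.
#'
#' @param display A `sampled_display` (or `dot_shape`).
#' @return An object of class `raw_projection` with integer vectors
#'   `row_counts` (length = grid rows) and `col_counts` (length = grid
#'   columns); both sum to the number of lit dots.
#' @examples
#' shp <- generate_inventory(1, seed = 1)[[1]]
#' pr <- projection_counts(full_display(shp))
#' length(pr$row_counts) + length(pr$col_counts)  # 128 on the default grid
#' @export
projection_counts <- function(display) {
  d <- display_dots(display)
  if (nrow(d) == 0L) stop("cannot project an empty display")
  g <- if (is.list(display) && !is.null(display$grid)) display$grid else grid_spec()
  sid <- if (is.list(display) && !is.null(display$shape_id)) display$shape_id else NA_character_
  structure(
    list(shape_id = sid,
         row_counts = tabulate(d[, 1L] + 1L, nbins = g$rows),
         col_counts = tabulate(d[, 2L] + 1L, nbins = g$cols)),
    class = "raw_projection"
  )
}

#' @export
print.raw_projection <- function(x, ...) {
  cat(sprintf("<raw_projection> '%s': %d row + %d column bins, %d dots\n",
              x$shape_id, length(x$row_counts), length(x$col_counts),
              sum(x$row_counts)))
  invisible(x)
}

#' Trim empty bins from a raw projection
#'
#' Deletes every empty row and column bin — interior zeros included — from
#' the concatenated (rows-then-columns) projection histogram, keeping only
#' bins that contained boundary dots and preserving their order. This is
#' what makes the scan encoding translation invariant: shifting a display
#' on the board only moves the zero bins.
#'
#' @param raw A `raw_projection`, or a numeric count vector.
#' @return Vector of the positive counts, in order; sums to twice the dot
#'   count (each dot is counted once in its row and once in its column).
#' @export
trim_empty <- function(raw) {
  v <- if (inherits(raw, "raw_projection")) c(raw$row_counts, raw$col_counts)
    else as.numeric(raw)
  if (all(v == 0)) stop("projection has no non-empty bins")
  v[v > 0]
}

#' Re-bin a count sequence by fractional interval overlap
#'
#' Aggregates a length-`L` sequence of unit-width bins into `B` equal-width
#' target bins: source bin `i` (covering `[i, i+1)`) contributes to target
#' bin `j` (covering `[jL/B, (j+1)L/B)`) in proportion to their overlap.
#' Total mass is conserved exactly. Implemented via the piecewise-linear
#' cumulative mass function evaluated at the target bin edges.
#'
#' @param counts Non-empty numeric vector (typically trimmed projection
#'   counts).
#' @param B Number of target bins (default 20).
#' @return Length-`B` non-negative vector with `sum(out) == sum(counts)`.
#' @examples
#' rebin(c(1, 2, 3, 4), B = 2)  # c(3, 7)
#' @export
rebin <- function(counts, B = 20L) {
  counts <- as.numeric(counts)
  L <- length(counts)
  if (L < 1L) stop("cannot re-bin an empty sequence")
  if (B < 1L) stop("B must be at least 1")
  cs <- c(0, cumsum(counts))
  cmf <- function(t) { # cumulative mass up to position t in [0, L]
    i <- pmin(pmax(floor(t), 0), L)
    frac <- t - i
    cs[i + 1L] + ifelse(i < L, frac * counts[pmin(i + 1L, L)], 0)
  }
  edges <- (0:B) * (L / B)
  diff(cmf(edges))
}

#' Normalize histogram bins to unit total mass
#'
#' @param bins Numeric vector with positive total mass.
#' @return `bins / sum(bins)`; sums to 1 within 1e-9. Idempotent.
#' @export
normalize_bins <- function(bins) {
  s <- sum(bins)
  if (!is.finite(s) || s <= 0) stop("bins must have positive total mass")
  bins / s
}

#' Scan-encode a display
#'
#' The full scan-encoding pipeline: count dots per row and per column
#' ([projection_counts()]), delete all empty bins ([trim_empty()]), re-bin
#' the trimmed sequence to `B` bins ([rebin()]), and normalize the bin
#' heights to sum to 1 ([normalize_bins()]). With `rebin_mode = "joint"`
#' (the default) the trimmed rows-then-columns concatenation is re-binned
#' jointly into `B` bins; `"split"` re-bins trimmed rows and trimmed
#' columns separately into `B/2` bins each and concatenates.
#'
#' The resulting histogram is exactly translation invariant and, after
#' normalization, approximately size invariant. It is not rotation
#' invariant: rotation exchanges row and column structure.
#'
#' @param display A `sampled_display` (or `dot_shape`).
#' @param B Number of final bins (default 20; must be even for `"split"`).
#' @param rebin_mode `"joint"` or `"split"`.
#' @return An object of class `scan_histogram` with fields `shape_id`,
#'   `bins` (length `B`, summing to 1) and `trimmed_length` (number of
#'   non-empty raw bins retained).
#' @examples
#' shp <- generate_inventory(1, seed = 1)[[1]]
#' h <- scan_encode(full_display(shp))
#' sum(h$bins)
#' @export
scan_encode <- function(display, B = 20L, rebin_mode = c("joint", "split")) {
  rebin_mode <- match.arg(rebin_mode)
  raw <- projection_counts(display)
  if (rebin_mode == "joint") {
    trimmed <- trim_empty(raw)
    bins <- rebin(trimmed, B)
    tl <- length(trimmed)
  } else {
    if (B %% 2L != 0L) stop("split re-binning needs an even B")
    tr <- trim_empty(raw$row_counts)
    tc <- trim_empty(raw$col_counts)
    bins <- c(rebin(tr, B %/% 2L), rebin(tc, B %/% 2L))
    tl <- length(tr) + length(tc)
  }
  structure(
    list(shape_id = raw$shape_id,
         bins = normalize_bins(bins),
         trimmed_length = as.integer(tl),
         B = as.integer(B),
         rebin_mode = rebin_mode),
    class = "scan_histogram"
  )
}

#' @export
print.scan_histogram <- function(x, ...) {
  cat(sprintf("<scan_histogram> '%s': %d bins (%s re-binning), trimmed length %d\n",
              x$shape_id, x$B, x$rebin_mode, x$trimmed_length))
  invisible(x)
}

#' @export
plot.scan_histogram <- function(x, ...) {
  graphics::barplot(x$bins, names.arg = seq_along(x$bins) - 1L,
                    xlab = "bin", ylab = "weight", main = x$shape_id, ...)
}

#' Sum-of-squared-differences between two scan histograms
#'
#' \eqn{\sum_i (a_i - b_i)^2} over the normalized bins; symmetric,
#' non-negative, zero exactly for identical histograms.
#'
#' @param a,b `scan_histogram` objects (or bare numeric bin vectors) with
#'   equal bin counts.
#' @return Non-negative similarity value (0 = identical; larger = more
#'   dissimilar).
#' @export
scan_similarity <- function(a, b) {
  av <- if (inherits(a, "scan_histogram")) a$bins else as.numeric(a)
  bv <- if (inherits(b, "scan_histogram")) b$bins else as.numeric(b)
  if (length(av) != length(bv)) stop("histograms have different bin counts")
  sum_sq_diff(av, bv)
}

#' All-pairs scan similarity over an inventory
#'
#' Pairs each encoded shape with each other shape once, giving
#' `n(n-1)/2` records (114,960 for a 480-shape inventory).
#'
#' @param inventory A list of `scan_histogram` objects (length at least 2).
#' @return Data frame with columns `id_a`, `id_b`, `value`, one row per
#'   unordered pair, in inventory order.
#' @export
all_pair_similarities <- function(inventory) {
  n <- length(inventory)
  if (n < 2L) stop("need at least 2 histograms to form pairs")
  ids <- vapply(inventory, function(h) h$shape_id, character(1L))
  M <- do.call(rbind, lapply(inventory, function(h) h$bins))
  D <- as.matrix(stats::dist(M))^2   # squared Euclidean = SSD
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  data.frame(id_a = ids[i], id_b = ids[j], value = D[cbind(i, j)],
             stringsAsFactors = FALSE)
}

#' Rank pair similarities and select pairs at equal rank intervals
#'
#' Sorts the pair similarities ascending (ties broken lexicographically by
#' id pair) to build the similarity scale, then selects `m` pairs at equal
#' intervals across the ranked values: ranks `round(k (P-1)/(m-1)) + 1` for
#' `k = 0, ..., m-1`, so both the most similar and the most dissimilar pair
#' are always included and selected rank gaps differ by at most one.
#' Duplicate selections (possible when `m` approaches `P`) are dropped with
#' a warning.
#'
#' @param pairs Data frame from [all_pair_similarities()].
#' @param m Number of pairs to select (`2 <= m <= nrow(pairs)`).
#' @return An object of class `ranked_scale`: list with `ranked` (all pairs
#'   with a `rank` column, ascending) and `selected` (the `m` chosen rows).
#' @examples
#' inv <- generate_inventory(10, seed = 1)
#' hs <- lapply(inv, function(s) scan_encode(full_display(s)))
#' rs <- rank_and_select(all_pair_similarities(hs), m = 5)
#' rs$selected$rank
#' @export
rank_and_select <- function(pairs, m) {
  P <- nrow(pairs)
  if (m < 2L) stop("m must be at least 2")
  if (m > P) stop("m cannot exceed the number of pairs")
  ord <- order(pairs$value, pairs$id_a, pairs$id_b)
  ranked <- pairs[ord, , drop = FALSE]
  ranked$rank <- seq_len(P)
  rownames(ranked) <- NULL
  idx <- round((0:(m - 1L)) * (P - 1L) / (m - 1L)) + 1L
  if (anyDuplicated(idx)) {
    warning("equal-interval selection produced duplicate ranks; duplicates dropped")
    idx <- unique(idx)
  }
  structure(
    list(ranked = ranked, selected = ranked[idx, , drop = FALSE]),
    class = "ranked_scale"
  )
}

#' @export
print.ranked_scale <- function(x, ...) {
  cat(sprintf("<ranked_scale> %d ranked pairs (range %.4g - %.4g), %d selected\n",
              nrow(x$ranked), min(x$ranked$value), max(x$ranked$value),
              nrow(x$selected)))
  invisible(x)
}

#' @export
plot.ranked_scale <- function(x, ...) {
  graphics::plot(x$ranked$rank, x$ranked$value, type = "l",
                 xlab = "rank", ylab = "scan similarity (SSD)",
                 main = "Ranked pair-similarity scale", ...)
  graphics::points(x$selected$rank, x$selected$value, pch = 16, cex = 0.5,
                   col = "red3")
}
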