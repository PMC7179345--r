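# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. All randomized
# operations in the package route through this so that identical
# (inputs, seed) give byte-identical output regardless of ambient state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# (row, col) coordinate matrices are stored as 2-column integer matrices,
# 0-based, row 0 at top (raster convention; stated in every serialized file).
as_coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L, byrow = TRUE)
  if (ncol(x) != 2L) stop("coordinates must be a 2-column (row, col) matrix")
  storage.mode(x) <- "integer"
  dimnames(x) <- list(NULL, c("row", "col"))
  x
}

coords_on_grid <- function(coords, grid) {
  coords[, 1L] >= 0L & coords[, 1L] < grid$rows &
    coords[, 2L] >= 0L & coords[, 2L] < grid$cols
}

dedupe_coords <- function(coords) {
  coords[!duplicated(coords[, 1L] * 1e6 + coords[, 2L]), , drop = FALSE]
}

# angle of points about a center, degrees in [0, 360), measured
# counterclockwise from the positive column axis (row 0 at top, so the
# visual "up" direction is decreasing row index)
coord_angle_deg <- function(coords, center) {
  dy <- -(coords[, 1L] - center[1L])
  dx <- coords[, 2L] - center[2L]
  (atan2(dy, dx) * 180 / pi) %% 360
}

# smallest absolute circular difference between two angles in degrees
angle_diff_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

sum_sq_diff <- function(a, b) sum((a - b)^2)
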