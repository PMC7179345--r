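# Serialization. Every file states the raster convention in a header:
# coordinates are 0-based (row, col), row-major, row 0 at top.

COORD_CONVENTION <- "0-based (row, col), row-major, row 0 at top"

grid_to_list <- function(g) g[c("rows", "cols", "dot_pitch", "dot_diameter")]

#' Read and write shapes and displays as JSON
#'
#' A shape file holds `{shape_id, grid, boundary}`; a display file adds
#' `{dots, density, sampling_mode, transform, partial}`. Both carry a
#' `coordinate_convention` header field.
#'
#' @param shape A [dot_shape()].
#' @param display A `sampled_display`.
#' @param path File path.
#' @return The written path (write), or the reconstructed object (read).
#' @name shape_io
NULL

#' @rdname shape_io
#' @export
write_shape_json <- function(shape, path) {
  obj <- list(coordinate_convention = COORD_CONVENTION,
              shape_id = shape$shape_id,
              grid = grid_to_list(shape$grid),
              boundary = unname(apply(shape$boundary, 1L, as.integer,
                                      simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname shape_io
#' @export
read_shape_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- do.call(grid_spec, as.list(obj$grid))
  dot_shape(obj$shape_id, as_coord_matrix(obj$boundary), g)
}

#' @rdname shape_io
#' @export
write_display_json <- function(display, path) {
  obj <- list(coordinate_convention = COORD_CONVENTION,
              shape_id = display$shape_id,
              grid = grid_to_list(display$grid),
              dots = unname(apply(display$dots, 1L, as.integer,
                                  simplify = FALSE)),
              density = display$density,
              sampling_mode = display$sampling_mode,
              transform = display$transform,
              partial = display$partial)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname shape_io
#' @export
read_display_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- do.call(grid_spec, as.list(obj$grid))
  new_sampled_display(obj$shape_id, g, as_coord_matrix(obj$dots),
                      density = obj$density,
                      sampling_mode = obj$sampling_mode,
                      transform = as.list(obj$transform),
                      partial = as.list(obj$partial))
}

#' Flat CSV export of shape boundaries
#'
#' One row per boundary dot: `shape_id,row,col,order` (order is the 1-based
#' position along the loop). A `#` comment line states the coordinate
#' convention.
#'
#' @param shapes A list of [dot_shape()] objects.
#' @param path File path.
#' @return The path, invisibly.
#' @export
shapes_to_csv <- function(shapes, path) {
  rows <- do.call(rbind, lapply(shapes, function(s) {
    data.frame(shape_id = s$shape_id,
               row = s$boundary[, 1L], col = s$boundary[, 2L],
               order = seq_len(nrow(s$boundary)))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# coordinates:", COORD_CONVENTION), con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' @rdname shapes_to_csv
#' @export
shapes_from_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  lapply(split(df, df$shape_id), function(d) {
    d <- d[order(d$order), ]
    dot_shape(d$shape_id[1L], cbind(d$row, d$col))
  })
}

#' Write centroid signatures / scan histograms / pair similarities as CSV
#'
#' Signature files: `shape_id,n_bins,scale_normalize,mean_radius,bin_0..`.
#' Histogram files: `shape_id,trimmed_length,bin_0..`. Pair files:
#' `id_a,id_b,similarity,rank`.
#'
#' @param signatures List of `centroid_signature` objects.
#' @param histograms List of `scan_histogram` objects.
#' @param scale A `ranked_scale` (or pair data frame with a `rank` column).
#' @param path File path.
#' @return The path, invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_signatures_csv <- function(signatures, path) {
  df <- do.call(rbind, lapply(signatures, function(s) {
    bins <- as.data.frame(as.list(s$bins))
    names(bins) <- paste0("bin_", seq_along(s$bins) - 1L)
    cbind(data.frame(shape_id = s$shape_id, n_bins = s$n_bins,
                     scale_normalize = s$scale_normalize,
                     mean_radius = s$mean_radius), bins)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
write_histograms_csv <- function(histograms, path) {
  df <- do.call(rbind, lapply(histograms, function(h) {
    bins <- as.data.frame(as.list(h$bins))
    names(bins) <- paste0("bin_", seq_along(h$bins) - 1L)
    cbind(data.frame(shape_id = h$shape_id,
                     trimmed_length = h$trimmed_length), bins)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
write_pairs_csv <- function(scale, path) {
  df <- if (inherits(scale, "ranked_scale")) scale$ranked else scale
  out <- data.frame(id_a = df$id_a, id_b = df$id_b,
                    similarity = df$value, rank = df$rank)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Render a display as a raster image
#'
#' One pixel per grid cell, lit dots white on black. `render_pgm()` writes
#' a binary PGM (P5); `render_png()` writes a PNG (requires the `png`
#' package).
#'
#' @param display A `sampled_display` (or `dot_shape`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
render_pgm <- function(display, path) {
  img <- display_raster(display)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", sprintf("# dotshape render; coordinates: %s", COORD_CONVENTION),
               sprintf("%d %d", ncol(img), nrow(img)), "255"), con)
  writeBin(as.raw(t(img)), con)
  invisible(path)
}

#' @rdname render_pgm
#' @export
render_png <- function(display, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("render_png needs the 'png' package")
  img <- display_raster(display)
  png::writePNG(img / 255, path)
  invisible(path)
}

display_raster <- function(display) {
  d <- display_dots(display)
  g <- if (is.list(display) && !is.null(display$grid)) display$grid else grid_spec()
  img <- matrix(0L, nrow = g$rows, ncol = g$cols)
  img[cbind(d[, 1L] + 1L, d[, 2L] + 1L)] <- 255L
  img
}

#' Write a trial log and summary report for a pipeline run
#'
#' The trial log is a CSV (`trial,pair_a,pair_b,is_same,similarity,response`);
#' the report is a JSON file with the design parameters, SDT indices and
#' regression fit. Intermediate tables (shape boundaries, scan histograms,
#' ranked pairs) are written alongside.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  shapes_to_csv(report$inventory, file.path(dir, "shapes.csv"))
  write_histograms_csv(report$histograms, file.path(dir, "scan_histograms.csv"))
  write_pairs_csv(report$scale, file.path(dir, "ranked_pairs.csv"))
  rec <- report$records
  log <- data.frame(respondent = rec$respondent, trial = rec$trial,
                    pair_a = rec$target_id, pair_b = rec$comparison_id,
                    is_same = rec$is_same, similarity = rec$similarity,
                    response = rec$response)
  utils::write.csv(log, file.path(dir, "trials.csv"), row.names = FALSE)
  des <- report$design$trials
  summary <- list(
    design = list(n_trials = nrow(des),
                  n_respondents = length(report$respondents),
                  n_same = sum(des$is_same), n_diff = sum(!des$is_same),
                  target_density = report$design$target_density,
                  comparison_density = report$design$comparison_density,
                  similarity_scale_max = report$similarity_scale_max),
    sdt = report$sdt[c("n_same", "n_diff", "hits", "false_alarms",
                       "H", "F", "d_prime", "pc_max")],
    regression = list(intercept = report$regression$intercept,
                      slope = report$regression$slope,
                      ci95_intercept = report$regression$ci95_intercept,
                      ci95_slope = report$regression$ci95_slope,
                      r_squared = report$regression$r_squared)
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
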