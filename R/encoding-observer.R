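#' Simulate an observer driven by measured encoding similarity
#'
#' Unlike [simulate_responses()], whose same-trials sit at similarity 0 by
#' design, this observer measures the scan similarity between the encoded
#' target display (at the design's target density) and the encoded
#' comparison display (sampled afresh at the design's comparison density)
#' on every trial, and responds through the same linear ramp and lapse.
#' Because low-density comparison encodings are noisy, match performance
#' degrades as comparison density drops — the density-sweep analog of the
#' behavioral task.
#'
#' @param design An `experiment_design`.
#' @param shapes Named list (or plain list) of [dot_shape()] objects
#'   covering every id in the design.
#' @param observer An [observer_params()].
#' @param similarity_scale_max Positive scale maximum for the ramp.
#' @param B,rebin_mode Scan-encoding parameters ([scan_encode()]).
#' @param seed Integer seed for the comparison-density sampling.
#' @return Trial records as in [simulate_responses()], with `similarity`
#'   holding the measured encoding similarity.
#' @export
simulate_encoding_responses <- function(design, shapes, observer,
                                        similarity_scale_max,
                                        B = 20L, rebin_mode = "joint",
                                        seed = 1L) {
  if (similarity_scale_max <= 0) stop("similarity_scale_max must be positive")
  ids <- vapply(shapes, `[[`, "", "shape_id")
  names(shapes) <- ids
  tr <- design$trials
  enc_target <- new.env(parent = emptyenv())
  enc_one <- function(id, density, samp_seed) {
    shp <- shapes[[id]]
    if (is.null(shp)) stop("design references unknown shape id: ", id)
    disp <- sample_density(shp, density, mode = "even", seed = samp_seed)
    scan_encode(disp, B = B, rebin_mode = rebin_mode)
  }
  samp_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2L, 2L * nrow(tr)))
  s <- vapply(seq_len(nrow(tr)), function(i) {
    ta <- enc_one(tr$target_id[i], design$target_density, samp_seeds[2L * i - 1L])
    co <- enc_one(tr$comparison_id[i], design$comparison_density, samp_seeds[2L * i])
    scan_similarity(ta, co)
  }, numeric(1L))
  p0 <- observer$p_same_at_zero
  pm <- observer$p_same_at_max
  p <- pmin(pmax(p0 + (pm - p0) * s / similarity_scale_max, 0), 1)
  with_seed(observer$seed, {
    intended <- stats::rbinom(nrow(tr), 1L, p) == 1L
    flip <- stats::rbinom(nrow(tr), 1L, observer$lapse) == 1L
    out <- tr
    out$similarity <- s
    out$response <- ifelse(xor(intended, flip), "same", "different")
    out
  })
}
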