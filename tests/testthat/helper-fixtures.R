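# shared fixtures, built in code

# axis-aligned square ring: 4*size - 4 dots, a minimal hand-checkable loop
square_loop <- function(top = 10L, left = 10L, size = 4L, grid = grid_spec(),
                        id = "square") {
  r2 <- top + size - 1L
  c2 <- left + size - 1L
  b <- rbind(
    cbind(top, left:c2),                       # top edge, left -> right
    cbind((top + 1L):r2, c2),                  # right edge, down
    cbind(r2, (c2 - 1L):left),                 # bottom edge, right -> left
    if (size > 2L) cbind((r2 - 1L):(top + 1L), left)  # left edge, up
  )
  dot_shape(id, b, grid)
}

# rasterized circle (amplitude 0 blob)
circle_shape <- function(seed = 7L, grid = grid_spec()) {
  generate_inventory(1L, seed = seed, grid = grid, amplitude = 0)[[1L]]
}

# small blobs that still fit the default board after scaling x2:
# generated on a 28 x 28 board, re-homed to the 64 x 64 board and centered
small_shapes <- function(n, seed = 1L) {
  inv <- generate_inventory(n, seed = seed, grid = grid_spec(28L, 28L))
  lapply(inv, function(s)
    dot_shape(s$shape_id, s$boundary + 18L, grid_spec()))
}

# lazily built, cached large fixtures used by the acceptance checks
.cache <- new.env(parent = emptyenv())

inventory480 <- function() {
  if (is.null(.cache$inv)) .cache$inv <- generate_inventory(480L, seed = 1L)
  .cache$inv
}

hists480 <- function() {
  if (is.null(.cache$hists))
    .cache$hists <- lapply(inventory480(), function(s) scan_encode(full_display(s)))
  .cache$hists
}

pairs480 <- function() {
  if (is.null(.cache$pairs)) .cache$pairs <- all_pair_similarities(hists480())
  .cache$pairs
}

# independent brute-force oracle: re-bin by explicit interval intersection
rebin_oracle <- function(counts, B) {
  L <- length(counts)
  out <- numeric(B)
  for (j in seq_len(B)) {
    lo <- (j - 1) * L / B
    hi <- j * L / B
    for (i in seq_len(L)) {
      ov <- max(0, min(i, hi) - max(i - 1, lo))
      out[j] <- out[j] + counts[i] * ov
    }
  }
  out
}

# fabricate trial records with exact per-pair response proportions
records_with_proportions <- function(sims, props, n_per_pair = 10L) {
  stopifnot(length(sims) == length(props),
            all(abs(props * n_per_pair - round(props * n_per_pair)) < 1e-9))
  do.call(rbind, lapply(seq_along(sims), function(i) {
    k <- round(props[i] * n_per_pair)
    data.frame(
      trial = NA_integer_,
      target_id = sprintf("t%02d", i), comparison_id = sprintf("c%02d", i),
      is_same = FALSE, similarity = sims[i],
      response = c(rep("same", k), rep("different", n_per_pair - k)),
      stringsAsFactors = FALSE)
  }))
}

# minimal records with given hit / false-alarm counts
sdt_records <- function(hits, n_same, fas, n_diff) {
  data.frame(
    trial = NA_integer_,
    target_id = "a",
    comparison_id = rep(c("a", "b"), c(n_same, n_diff)),
    is_same = rep(c(TRUE, FALSE), c(n_same, n_diff)),
    similarity = rep(c(0, 1), c(n_same, n_diff)),
    response = c(rep(c("same", "different"), c(hits, n_same - hits)),
                 rep(c("same", "different"), c(fas, n_diff - fas))),
    stringsAsFactors = FALSE)
}
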