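test_that("generated inventories satisfy the boundary-loop invariants and are reproducible", {
  inv <- generate_inventory(25, seed = 11)
  expect_length(inv, 25)
  for (s in inv) expect_silent(validate_dot_shape(s))
  expect_false(anyDuplicated(vapply(inv, `[[`, "", "shape_id")) > 0)
  expect_identical(inv, generate_inventory(25, seed = 11))
  expect_false(identical(inv, generate_inventory(25, seed = 12)))
})

test_that("zero-amplitude blobs rasterize to circles: near-constant centroid distance", {
  for (seed in c(3, 7, 21)) {
    s <- circle_shape(seed)
    b <- s$boundary
    cen <- colMeans(b)
    d <- sqrt((b[, 1] - cen[1])^2 + (b[, 2] - cen[2])^2)
    expect_lt(max(abs(d - mean(d))), 0.75)
  }
})

test_that("generator rejects amplitudes incompatible with the grid", {
  expect_error(generate_inventory(1, seed = 1, amplitude = 1.0), "amplitude")
})

test_that("density sampling selects round(density * N) dots, evenly in even mode", {
  shp <- square_loop(size = 26)  # N = 100
  expect_equal(nrow(shp$boundary), 100)

  d12 <- sample_density(shp, 0.12, seed = 5)
  expect_equal(nrow(d12$dots), 12)

  full <- sample_density(shp, 1.0, seed = 5)
  expect_identical(full$dots, shp$boundary)

  # even mode at density 0.25: successive boundary positions 4 apart everywhere
  d25 <- sample_density(shp, 0.25, mode = "even", seed = 9)
  pos <- match(paste(d25$dots[, 1], d25$dots[, 2]),
               paste(shp$boundary[, 1], shp$boundary[, 2]))
  gaps <- diff(c(sort(pos), sort(pos)[1] + 100))
  expect_true(all(gaps == 4))

  expect_error(sample_density(shp, 0), "density")
  expect_error(sample_density(shp, 1.2), "density")
})

test_that("density sampling is monotone in density and seed-reproducible", {
  shp <- circle_shape(2)
  counts <- vapply(c(0.05, 0.12, 0.25, 0.5, 0.75, 1),
                   function(d) nrow(sample_density(shp, d, seed = 4)$dots),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  for (mode in c("even", "random")) {
    a <- sample_density(shp, 0.3, mode = mode, seed = 17)
    b <- sample_density(shp, 0.3, mode = mode, seed = 17)
    expect_identical(a$dots, b$dots)
  }
})

test_that("transforms behave rigidly: identity, translation, double 180-degree rotation", {
  disp <- full_display(circle_shape(5))

  ident <- apply_transform(disp, 0, 0, 0, 1)
  expect_identical(ident$dots, disp$dots)

  shifted <- apply_transform(disp, dx = 5, dy = -3)
  cheb <- function(d) {
    dr <- outer(d[, 1], d[, 1], "-"); dc <- outer(d[, 2], d[, 2], "-")
    pmax(abs(dr), abs(dc))
  }
  expect_identical(cheb(shifted$dots), cheb(disp$dots))
  expect_equal(shifted$transform$dx, 5)

  twice <- apply_transform(apply_transform(disp, rotation = 180), rotation = 180)
  # each recovered dot within 1 grid step of an original dot
  for (i in seq_len(nrow(twice$dots))) {
    dd <- pmax(abs(disp$dots[, 1] - twice$dots[i, 1]),
               abs(disp$dots[, 2] - twice$dots[i, 2]))
    expect_lte(min(dd), 1)
  }
})

test_that("off-grid transforms raise an error listing offending coordinates", {
  disp <- full_display(circle_shape(5))
  expect_error(apply_transform(disp, dx = 60), "off the .* grid")
  expect_error(apply_transform(disp, scale = 3), "dot")
})

test_that("half-perimeter partials keep one contiguous arc of round(N/2) dots", {
  shp <- square_loop(top = 5, left = 5, size = 51)  # N = 200
  expect_equal(nrow(shp$boundary), 200)
  half <- make_partial(shp, "half", angle = 30, density = 1)
  expect_equal(nrow(half$dots), 100)
  # consecutive kept dots remain 8-adjacent: a contiguous run along the loop
  d <- half$dots
  steps <- pmax(abs(diff(d[, 1])), abs(diff(d[, 2])))
  expect_true(all(steps == 1))
  expect_identical(half$partial$kind, "half")
})

test_that("opposite-quarters arcs subtend about 180 degrees at the full centroid", {
  for (seed in c(1, 4)) {
    shp <- circle_shape(seed)
    n <- nrow(shp$boundary)
    oq <- make_partial(shp, "opposite_quarters", angle = 45, density = 1)
    q <- round(n / 4)
    expect_equal(nrow(oq$dots), 2 * q)
    cen <- centroid(shp)
    mid1 <- colMeans(oq$dots[seq_len(q), , drop = FALSE])
    mid2 <- colMeans(oq$dots[(q + 1):(2 * q), , drop = FALSE])
    a1 <- atan2(-(mid1[1] - cen[1]), mid1[2] - cen[2]) * 180 / pi
    a2 <- atan2(-(mid2[1] - cen[1]), mid2[2] - cen[2]) * 180 / pi
    sep <- abs((a1 - a2) %% 360)
    sep <- min(sep, 360 - sep)
    expect_lt(abs(sep - 180), 10)
  }
})

test_that("a half-perimeter display of a circle displaces the displayed centroid", {
  shp <- circle_shape(9)
  for (angle in c(0, 90, 222)) {
    half <- make_partial(shp, "half", angle = angle, density = 1)
    expect_gt(centroid_displacement(shp, half), 0.5)
  }
})

test_that("two opposite half-perimeter arcs reconstruct the full boundary up to rounding", {
  shp <- circle_shape(13)
  n <- nrow(shp$boundary)
  h1 <- make_partial(shp, "half", angle = 70, density = 1)
  h2 <- make_partial(shp, "half", angle = 250, density = 1)
  got <- unique(rbind(h1$dots, h2$dots))
  expect_gte(nrow(got), n - 3)
  expect_true(all(paste(got[, 1], got[, 2]) %in%
                    paste(shp$boundary[, 1], shp$boundary[, 2])))
})

test_that("partial displays apply density sampling within the kept arcs", {
  shp <- square_loop(top = 5, left = 5, size = 51)  # N = 200
  half <- make_partial(shp, "half", angle = 0, density = 0.2, seed = 2)
  expect_equal(nrow(half$dots), 20)  # round(0.2 * 100)
  oq <- make_partial(shp, "opposite_quarters", angle = 0, density = 0.5, seed = 2)
  expect_equal(nrow(oq$dots), 2 * 25)
  expect_identical(make_partial(shp, "half", angle = 0, density = 0.2, seed = 2)$dots,
                   half$dots)
})

test_that("dot separation is queryable in degrees of arc", {
  shp <- square_loop(size = 26)
  full <- full_display(shp)
  sparse <- sample_density(shp, 0.1, seed = 1)
  expect_lt(min_dot_separation_deg(full), min_dot_separation_deg(sparse))
  expect_equal(min_dot_separation_deg(full), 9.2 / 60)
})
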