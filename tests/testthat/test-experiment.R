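make_pairs <- function(m, smax = 1) {
  data.frame(id_a = sprintf("a%03d", seq_len(m)),
             id_b = sprintf("b%03d", seq_len(m)),
             value = seq(0, smax, length.out = m),
             stringsAsFactors = FALSE)
}

test_that("designs contain one trial per pair plus the requested same-trials", {
  pairs <- make_pairs(300)
  des <- build_design(pairs, n_same = 90, seed = 1,
                      same_pool = sprintf("s%03d", 1:120))
  expect_s3_class(des, "experiment_design")
  expect_equal(nrow(des$trials), 390)
  expect_equal(sum(des$trials$is_same), 90)
  expect_true(all(des$trials$similarity[des$trials$is_same] == 0))
  expect_true(all(des$trials$target_id[!des$trials$is_same] !=
                    des$trials$comparison_id[!des$trials$is_same]))

  none <- build_design(pairs, n_same = 0, seed = 1)
  expect_equal(nrow(none$trials), 300)
  expect_true(all(!none$trials$is_same))

  expect_identical(build_design(pairs, n_same = 10, seed = 7)$trials,
                   build_design(pairs, n_same = 10, seed = 7)$trials)
  expect_false(identical(build_design(pairs, n_same = 10, seed = 7)$trials,
                         build_design(pairs, n_same = 10, seed = 8)$trials))

  bad <- pairs; bad$id_b[3] <- bad$id_a[3]
  expect_error(build_design(bad, n_same = 0), "same shape")

  reps <- build_design(pairs, n_same = 90, seed = 1, n_reps = 3)
  expect_equal(nrow(reps$trials), 3 * 300 + 90)
})

test_that("the simulated observer hits the printed ramp endpoints", {
  obs <- observer_params(lapse = 0, seed = 2)
  at <- function(s) {
    pairs <- make_pairs(2, smax = 1)
    pairs$value <- s
    des <- build_design(pairs, n_same = 0, seed = 1, n_reps = 2500)
    rec <- simulate_responses(des, obs, similarity_scale_max = 1)
    mean(rec$response == "same")
  }
  expect_lt(abs(at(0) - 0.7), 0.025)   # ~4 binomial SDs at n = 5000
  expect_lt(abs(at(1) - 0.2), 0.025)
})

test_that("a flat observer produces fair-coin responses", {
  obs <- observer_params(p_same_at_zero = 0.5, p_same_at_max = 0.5,
                         lapse = 0, seed = 3)
  pairs <- make_pairs(4, smax = 1)
  des <- build_design(pairs, n_same = 0, seed = 1, n_reps = 2500)
  rec <- simulate_responses(des, obs, similarity_scale_max = 1)
  expect_equal(nrow(rec), 10000)
  expect_equal(mean(rec$response == "same"), 0.5, tolerance = 0.02)
})

test_that("simulation validates its inputs", {
  pairs <- make_pairs(5)
  des <- build_design(pairs, n_same = 2, seed = 1)
  expect_error(simulate_responses(des, observer_params(), -1), "positive")
  des$trials$similarity[1] <- -0.1
  des$trials$is_same[1] <- FALSE
  expect_error(simulate_responses(des, observer_params(), 1), "non-negative")
  expect_error(observer_params(p_same_at_zero = 0.2, p_same_at_max = 0.7))
  expect_error(observer_params(lapse = 0.6))
})

test_that("equal hit and false-alarm rates give d-prime 0 and chance pc_max", {
  sdt <- sdt_summary(sdt_records(hits = 30, n_same = 60, fas = 30, n_diff = 60))
  expect_equal(sdt$d_prime, 0)
  expect_equal(sdt$pc_max, 0.5)
})

test_that("sdt_summary recovers the Gaussian closed form at large n", {
  # uncorrected H = Phi(1), F = Phi(-1) -> d' = 2, pc_max = Phi(1)
  n <- 10000
  sdt <- sdt_summary(sdt_records(hits = round(pnorm(1) * n), n_same = n,
                                 fas = round(pnorm(-1) * n), n_diff = n))
  expect_equal(sdt$d_prime, 2, tolerance = 0.01)
  expect_equal(sdt$pc_max, pnorm(1), tolerance = 0.005)
})

test_that("the log-linear correction keeps d-prime finite at ceiling", {
  rec <- sdt_records(hits = 50, n_same = 50, fas = 50, n_diff = 50)
  sdt <- sdt_summary(rec)  # every response "same"
  expect_true(is.finite(sdt$d_prime))
  expect_lt(sdt$pc_max, 1)
  expect_error(sdt_summary(rec[rec$is_same, ]), "different-trial")
})

test_that("pc_max rises with the hit rate at fixed false-alarm rate", {
  pcs <- vapply(c(30, 40, 48), function(h)
    sdt_summary(sdt_records(h, 60, 15, 60))$pc_max, numeric(1))
  expect_true(all(diff(pcs) > 0))
})

test_that("the similarity regression interpolates exact proportions", {
  sims <- seq(0, 1, by = 0.2)
  props <- 0.7 - 0.5 * sims  # 0.7 at zero declining to 0.2
  fit <- fit_similarity_regression(records_with_proportions(sims, props))
  expect_equal(fit$intercept, 0.7, tolerance = 1e-12)
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$ci95_intercept[1] <= fit$intercept &&
                fit$intercept <= fit$ci95_intercept[2])

  flat <- fit_similarity_regression(
    records_with_proportions(sims, rep(0.4, length(sims))))
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  expect_error(fit_similarity_regression(
    records_with_proportions(c(1, 1, 1), c(0.1, 0.2, 0.3))), "degenerate")
})

test_that("regression methods expose coefficients, intervals and predictions", {
  sims <- seq(0, 1, by = 0.25)
  fit <- fit_similarity_regression(
    records_with_proportions(sims, c(0.7, 0.6, 0.5, 0.4, 0.2)))
  expect_equal(unname(coef(fit)),
               unname(coef(fit$fit)), tolerance = 1e-12)
  ci <- confint(fit)
  expect_equal(dim(ci), c(2L, 2L))
  expect_true(ci[2, 1] <= fit$slope && fit$slope <= ci[2, 2])
  pred <- predict(fit, newdata = data.frame(similarity = 0.5))
  expect_equal(unname(pred), fit$intercept + 0.5 * fit$slope, tolerance = 1e-12)
  expect_equal(length(residuals(fit)), length(sims))
})

test_that("the simulated observer's generating line is recovered by the regression", {
  obs <- observer_params(seed = 5)
  pairs <- make_pairs(150, smax = 2)
  des <- build_design(pairs, n_same = 0, seed = 2, n_reps = 40)
  rec <- simulate_responses(des, obs, similarity_scale_max = 2)
  fit <- fit_similarity_regression(rec)
  lapse <- obs$lapse
  expect_lt(abs(fit$intercept - (0.7 * (1 - 2 * lapse) + lapse)), 0.05)
  expect_lt(abs(fit$slope - (0.2 - 0.7) * (1 - 2 * lapse) / 2), 0.05)
  expect_lt(fit$ci95_slope[2], 0)  # decline is credibly negative
})

test_that("match performance does not improve as comparison density drops", {
  inv <- generate_inventory(24, seed = 9)
  hs <- lapply(inv, function(s) scan_encode(full_display(s)))
  sel <- rank_and_select(all_pair_similarities(hs), m = 40)$selected
  smax <- max(all_pair_similarities(hs)$value)
  mean_pc <- function(dens) {
    pcs <- vapply(1:6, function(k) {
      des <- build_design(sel, n_same = 20, comparison_density = dens,
                          seed = 100 + k,
                          same_pool = vapply(inv, `[[`, "", "shape_id"))
      obs <- observer_params(seed = 200 + k)
      rec <- simulate_encoding_responses(des, inv, obs, smax, seed = 300 + k)
      sdt_summary(rec)$pc_max
    }, numeric(1))
    mean(pcs)
  }
  pc <- vapply(c(0.25, 0.12, 0.05), mean_pc, numeric(1))
  expect_gte(pc[1], pc[2] - 0.02)
  expect_gte(pc[2], pc[3] - 0.02)
  expect_gt(pc[1], pc[3])
})

test_that("the end-to-end pipeline runs, reports, and is deterministic", {
  cfg <- pipeline_config(n_shapes = 10, m_pairs = 5, n_same = 4, seed = 3)
  rep1 <- run_pipeline(cfg)
  expect_equal(nrow(rep1$design$trials), 9)
  expect_equal(nrow(rep1$scale$ranked), 45)
  expect_s3_class(rep1$sdt, "sdt_summary")
  expect_s3_class(rep1$regression, "group_regression")
  expect_length(rep1$respondents, 8)
  expect_equal(nrow(rep1$regression$respondents), 8)
  rep2 <- run_pipeline(cfg)
  expect_identical(rep1$records, rep2$records)
  expect_identical(rep1$sdt, rep2$sdt)
  expect_identical(coef(rep1$regression), coef(rep2$regression))
})

test_that("pipeline errors carry their stage label", {
  expect_error(run_pipeline(pipeline_config(n_shapes = 3, m_pairs = 300)),
               "stage: rank_and_select")
})
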