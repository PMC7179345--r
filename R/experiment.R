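#' Simulated-observer parameters
#'
#' The simulated respondent answers "same" with a probability that declines
#' linearly in the target/comparison scan-similarity value: probability
#' `p_same_at_zero` for identical encodings (similarity 0) falling to
#' `p_same_at_max` at the top of the similarity scale, mixed with a lapse
#' rate that flips the intended response. The defaults (0.7 at zero, 0.2 at
#' the maximum) anchor the linear decline of match-judgment probability
#' observed across a ranked similarity scale.
#'
#' @param p_same_at_zero P("same") at similarity 0, in `[0, 1]`.
#' @param p_same_at_max P("same") at the scale maximum; must not exceed
#'   `p_same_at_zero`.
#' @param lapse Probability of flipping the intended response, in `[0, 0.5)`.
#' @param seed Integer seed for the observer's response draws.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(p_same_at_zero = 0.7, p_same_at_max = 0.2,
                            lapse = 0.02, seed = 1L) {
  if (p_same_at_zero < 0 || p_same_at_zero > 1 ||
      p_same_at_max < 0 || p_same_at_max > p_same_at_zero)
    stop("need 0 <= p_same_at_max <= p_same_at_zero <= 1")
  if (lapse < 0 || lapse >= 0.5) stop("lapse must lie in [0, 0.5)")
  structure(list(p_same_at_zero = p_same_at_zero,
                 p_same_at_max = p_same_at_max,
                 lapse = lapse, seed = as.integer(seed)),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("<observer_params> P(same): %.2f at s=0 -> %.2f at s=max, lapse %.2f\n",
              x$p_same_at_zero, x$p_same_at_max, x$lapse))
  invisible(x)
}

#' Build a same/different match-recognition design
#'
#' One "different" trial per selected similarity pair — one member shown as
#' the target at `target_density`, the other as the comparison at
#' `comparison_density`, with roles assigned at random — plus `n_same`
#' trials in which the same shape serves as both target and comparison
#' (similarity 0). Same-trial shapes are drawn from `same_pool`, preferring
#' shapes not already used in a pair. Trial order is shuffled. The default
#' densities follow the standard task: targets at 100%, comparisons
#' degraded to 12% to prevent discrimination of small differences.
#'
#' @param selected_pairs Data frame with columns `id_a`, `id_b`, `value`
#'   (e.g. `rank_and_select(...)$selected`).
#' @param n_same Number of same-shape trials (default 90).
#' @param target_density,comparison_density Display densities in `(0, 1]`.
#' @param seed Integer seed (role assignment, same-shape draw, shuffle).
#' @param same_pool Character vector of shape ids from which same-trials
#'   are drawn; defaults to the ids appearing in `selected_pairs`.
#' @param n_reps Number of presentations of each selected pair (default 1;
#'   larger values stabilize the per-pair response proportions used by
#'   [fit_similarity_regression()]).
#' @return An object of class `experiment_design`: list with `trials` (data
#'   frame `trial`, `target_id`, `comparison_id`, `is_same`, `similarity`)
#'   and the two densities.
#' @export
build_design <- function(selected_pairs, n_same = 90L, target_density = 1.0,
                         comparison_density = 0.12, seed = 1L,
                         same_pool = NULL, n_reps = 1L) {
  if (n_reps < 1L) stop("n_reps must be at least 1")
  if (target_density <= 0 || target_density > 1 ||
      comparison_density <= 0 || comparison_density > 1)
    stop("densities must lie in (0, 1]")
  if (any(selected_pairs$id_a == selected_pairs$id_b))
    stop("a 'different' trial cannot use the same shape as target and comparison")
  if (any(selected_pairs$value < 0)) stop("similarity values must be non-negative")
  pair_ids <- unique(c(selected_pairs$id_a, selected_pairs$id_b))
  if (is.null(same_pool)) same_pool <- pair_ids
  m <- nrow(selected_pairs)
  with_seed(seed, {
    flip <- stats::rbinom(m, 1L, 0.5) == 1L
    diff_trials <- data.frame(
      target_id = ifelse(flip, selected_pairs$id_b, selected_pairs$id_a),
      comparison_id = ifelse(flip, selected_pairs$id_a, selected_pairs$id_b),
      is_same = FALSE,
      similarity = selected_pairs$value,
      stringsAsFactors = FALSE
    )
    if (n_reps > 1L)
      diff_trials <- diff_trials[rep(seq_len(m), each = n_reps), , drop = FALSE]
    trials <- diff_trials
    if (n_same > 0L) {
      fresh <- setdiff(same_pool, pair_ids)
      pool <- if (length(fresh) >= n_same) fresh else same_pool
      if (length(pool) < n_same)
        stop("not enough shapes in same_pool for the requested same-trials")
      ids <- sample(pool, n_same)
      trials <- rbind(trials, data.frame(
        target_id = ids, comparison_id = ids, is_same = TRUE,
        similarity = 0, stringsAsFactors = FALSE))
    }
    trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
    trials <- cbind(trial = seq_len(nrow(trials)), trials)
    rownames(trials) <- NULL
    structure(list(trials = trials,
                   target_density = target_density,
                   comparison_density = comparison_density),
              class = "experiment_design")
  })
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %d trials (%d same, %d different); target %.0f%%, comparison %.0f%% density\n",
              nrow(x$trials), sum(x$trials$is_same), sum(!x$trials$is_same),
              100 * x$target_density, 100 * x$comparison_density))
  invisible(x)
}

#' Simulate an observer's same/different responses
#'
#' For each trial, the probability of responding "same" is the linear ramp
#' `clamp(p0 + (pmax - p0) * s / similarity_scale_max, 0, 1)` in the
#' trial's similarity value `s` (same-trials use `s = 0`), after which the
#' response is flipped with probability `lapse`. Draws are Bernoulli from
#' the observer's seed.
#'
#' @param design An `experiment_design`.
#' @param observer An [observer_params()].
#' @param similarity_scale_max Top of the similarity scale (positive);
#'   typically the maximum of the ranked scale the pairs were drawn from.
#' @return A data frame of trial records: `trial`, `target_id`,
#'   `comparison_id`, `is_same`, `similarity`, `response` (`"same"` /
#'   `"different"`).
#' @export
simulate_responses <- function(design, observer, similarity_scale_max) {
  if (!is.numeric(similarity_scale_max) || similarity_scale_max <= 0)
    stop("similarity_scale_max must be positive")
  tr <- design$trials
  s <- ifelse(tr$is_same, 0, tr$similarity)
  if (any(s < 0)) stop("similarity values must be non-negative")
  p0 <- observer$p_same_at_zero
  pm <- observer$p_same_at_max
  p <- pmin(pmax(p0 + (pm - p0) * s / similarity_scale_max, 0), 1)
  n <- nrow(tr)
  with_seed(observer$seed, {
    intended <- stats::rbinom(n, 1L, p) == 1L
    flip <- stats::rbinom(n, 1L, observer$lapse) == 1L
    same <- xor(intended, flip)
    out <- tr
    out$response <- ifelse(same, "same", "different")
    out
  })
}

#' Signal-detection summary of same/different responses
#'
#' A "same" response on a same-trial is a hit; on a different-trial, a
#' false alarm. Rates are corrected by the log-linear rule (add 0.5 to each
#' count and 1 to each denominator) so they never reach 0 or 1, then
#' \deqn{d' = z(H) - z(F), \qquad p(c)_{max} = \Phi(d'/2),}
#' the bias-free proportion correct an unbiased observer with the same
#' sensitivity would attain. `pc_max = 0.5` exactly when `H = F` (chance).
#'
#' @param records Trial records from [simulate_responses()] (needs at least
#'   one same and one different trial).
#' @return An object of class `sdt_summary` with counts, corrected rates
#'   `H` and `F`, `d_prime` and `pc_max`.
#' @examples
#' des <- list(trials = data.frame(
#'   trial = 1:4, target_id = c("a", "a", "a", "b"),
#'   comparison_id = c("a", "a", "b", "a"),
#'   is_same = c(TRUE, TRUE, FALSE, FALSE), similarity = c(0, 0, 1, 1)))
#' class(des) <- "experiment_design"
#' rec <- des$trials
#' rec$response <- c("same", "different", "different", "same")
#' sdt_summary(rec)
#' @export
sdt_summary <- function(records) {
  is_same <- records$is_same
  n_same <- sum(is_same)
  n_diff <- sum(!is_same)
  if (n_same < 1L || n_diff < 1L)
    stop("need at least one same-trial and one different-trial")
  said_same <- records$response == "same"
  hits <- sum(said_same & is_same)
  fas <- sum(said_same & !is_same)
  H <- (hits + 0.5) / (n_same + 1)
  F <- (fas + 0.5) / (n_diff + 1)
  d_prime <- stats::qnorm(H) - stats::qnorm(F)
  structure(
    list(n_same = n_same, n_diff = n_diff,
         hits = hits, false_alarms = fas,
         H = H, F = F, d_prime = d_prime,
         pc_max = stats::pnorm(d_prime / 2)),
    class = "sdt_summary"
  )
}

#' @export
print.sdt_summary <- function(x, ...) {
  cat("<sdt_summary>\n")
  cat(sprintf("  same-trials: %d (hits %d, H = %.3f)\n", x$n_same, x$hits, x$H))
  cat(sprintf("  diff-trials: %d (false alarms %d, F = %.3f)\n",
              x$n_diff, x$false_alarms, x$F))
  cat(sprintf("  d' = %.3f, p(c)max = %.3f\n", x$d_prime, x$pc_max))
  invisible(x)
}

#' Regress per-pair "same"-response proportion on scan similarity
#'
#' Groups the different-trial records by target/comparison pair, computes
#' the proportion of "same" responses per pair, and fits an ordinary
#' least-squares line of proportion on similarity value, with 95%
#' confidence intervals from the standard linear-model variance estimate.
#' This is the per-respondent regression of match judgment on the ranked
#' similarity scale; same-trials (similarity 0) are excluded from the fit
#' and summarized separately by [sdt_summary()].
#'
#' @param records Trial records from [simulate_responses()].
#' @return An object of class `similarity_regression` with `intercept`,
#'   `slope`, `ci95_intercept`, `ci95_slope`, `r_squared`, the per-pair
#'   data (`pairs`), and the underlying `lm` fit.
#' @export
fit_similarity_regression <- function(records) {
  d <- records[!records$is_same, , drop = FALSE]
  if (nrow(d) == 0L) stop("no different-trials to regress on")
  key <- paste(pmin(d$target_id, d$comparison_id),
               pmax(d$target_id, d$comparison_id), sep = "|")
  prop <- tapply(d$response == "same", key, mean)
  sim <- tapply(d$similarity, key, mean)
  pairs <- data.frame(pair = names(prop),
                      similarity = as.numeric(sim),
                      prop_same = as.numeric(prop),
                      n = as.integer(table(key)[names(prop)]),
                      stringsAsFactors = FALSE)
  if (length(unique(pairs$similarity)) < 3L)
    stop("degenerate design: need at least 3 distinct similarity values")
  fit <- stats::lm(prop_same ~ similarity, data = pairs)
  # noiseless proportions fit exactly; the perfect-fit advisory is expected
  quiet_perfect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  ci <- quiet_perfect(stats::confint(fit, level = 0.95))
  structure(
    list(intercept = unname(stats::coef(fit)[1L]),
         slope = unname(stats::coef(fit)[2L]),
         ci95_intercept = unname(ci[1L, ]),
         ci95_slope = unname(ci[2L, ]),
         r_squared = quiet_perfect(summary(fit))$r.squared,
         pairs = pairs,
         fit = fit),
    class = "similarity_regression"
  )
}

#' @export
print.similarity_regression <- function(x, ...) {
  cat("<similarity_regression> P(same) ~ similarity over",
      nrow(x$pairs), "pairs\n")
  cat(sprintf("  intercept %.3f  [%.3f, %.3f]\n",
              x$intercept, x$ci95_intercept[1L], x$ci95_intercept[2L]))
  cat(sprintf("  slope     %.3f  [%.3f, %.3f]\n",
              x$slope, x$ci95_slope[1L], x$ci95_slope[2L]))
  cat(sprintf("  R-squared %.3f\n", x$r_squared))
  invisible(x)
}

#' @export
coef.similarity_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.similarity_regression <- function(object, parm, level = 0.95, ...) {
  stats::confint(object$fit, level = level, ...)
}

#' @export
predict.similarity_regression <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.similarity_regression <- function(object, ...) {
  stats::residuals(object$fit)
}

#' @export
plot.similarity_regression <- function(x, ...) {
  p <- x$pairs
  graphics::plot(p$similarity, p$prop_same, pch = 16, cex = 0.6,
                 xlab = "scan similarity (SSD)", ylab = "P(judged same)",
                 ylim = c(0, 1), main = "Match judgment vs similarity", ...)
  xs <- seq(min(p$similarity), max(p$similarity), length.out = 100)
  pr <- stats::predict(x$fit, newdata = data.frame(similarity = xs),
                       interval = "confidence")
  graphics::lines(xs, pr[, "fit"], lwd = 2)
  graphics::lines(xs, pr[, "lwr"], lty = 2)
  graphics::lines(xs, pr[, "upr"], lty = 2)
}

#' Group-mean regression model across respondents
#'
#' Averages per-respondent [fit_similarity_regression()] fits into the
#' group model: the mean intercept and slope, with 95% confidence
#' intervals from the between-respondent variability (t distribution on
#' n - 1 degrees of freedom). With a single respondent the respondent's
#' own model-based intervals are passed through.
#'
#' @param fits A non-empty list of `similarity_regression` objects.
#' @return An object of class `group_regression` with `intercept`, `slope`,
#'   `ci95_intercept`, `ci95_slope`, `n_respondents`, and the per-respondent
#'   coefficient table `respondents`.
#' @export
group_regression <- function(fits) {
  if (length(fits) == 0L) stop("need at least one respondent fit")
  co <- t(vapply(fits, function(f) c(f$intercept, f$slope), numeric(2L)))
  colnames(co) <- c("intercept", "slope")
  n <- nrow(co)
  if (n == 1L) {
    ci_i <- fits[[1L]]$ci95_intercept
    ci_s <- fits[[1L]]$ci95_slope
  } else {
    tq <- stats::qt(0.975, df = n - 1L)
    sem <- apply(co, 2L, stats::sd) / sqrt(n)
    ci_i <- mean(co[, 1L]) + c(-1, 1) * tq * sem[1L]
    ci_s <- mean(co[, 2L]) + c(-1, 1) * tq * sem[2L]
  }
  structure(
    list(intercept = mean(co[, 1L]), slope = mean(co[, 2L]),
         ci95_intercept = ci_i, ci95_slope = ci_s,
         r_squared = mean(vapply(fits, `[[`, numeric(1L), "r_squared")),
         n_respondents = n,
         respondents = as.data.frame(co)),
    class = "group_regression"
  )
}

#' @export
print.group_regression <- function(x, ...) {
  cat(sprintf("<group_regression> mean model over %d respondent(s)\n",
              x$n_respondents))
  cat(sprintf("  intercept %.3f  [%.3f, %.3f]\n",
              x$intercept, x$ci95_intercept[1L], x$ci95_intercept[2L]))
  cat(sprintf("  slope     %.3f  [%.3f, %.3f]\n",
              x$slope, x$ci95_slope[1L], x$ci95_slope[2L]))
  invisible(x)
}

#' @export
coef.group_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}
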