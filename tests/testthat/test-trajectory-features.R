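make_fc <- function(times, fc) nfkb_trajectory(times, fc)

test_that("fold-change AUC clips below baseline and integrates above it", {
  tt <- seq(0, 180, by = 4)
  expect_equal(auc_fold_change(make_fc(tt, rep(1, length(tt)))), 0)
  # fc = 2 on [0, 60], 1 after: integrand 1 over 60 min, up to the trapezoid
  # at the step edge (one half-cell = 2 min)
  fc <- ifelse(tt <= 60, 2, 1); fc[1] <- 1
  # t = 0 must be 1; ramp the first sample only (costs another half-cell)
  expect_lt(abs(auc_fold_change(make_fc(tt, fc)) - 60), 4 + 1e-9)
  # below-baseline values are clipped, not subtracted
  low <- rep(0.5, length(tt)); low[1] <- 1
  expect_equal(auc_fold_change(make_fc(tt, low)), 0)
  # invariant to appending trailing baseline samples
  base <- make_fc(tt, pmax(1 + sin(tt / 30), 0.2) * c(1, rep(1, length(tt) - 1)))
  base$fold_change[1] <- 1
  longer <- nfkb_trajectory(c(tt, max(tt) + 4 * (1:5)),
                            c(base$fold_change, rep(1, 5)))
  expect_equal(auc_fold_change(longer), auc_fold_change(base))
  expect_gte(auc_fold_change(base), 0)
})

test_that("CI features match the analytic triangle", {
  tri <- make_triangular_ci(100, 100, smooth_window = 1)
  f <- ci_features(tri, adapt_fraction = 0.1)
  expect_equal(f$t_max, 28)
  # falling edge crosses 10% of peak at 100*(100-t)/72 = 10 => t = 92.8
  expect_lte(abs(f$t_adapt - 92.8), 4)
  expect_false(f$undefined)
  expect_false(f$right_censored)
  # all-zero control: AUC 0, features undefined
  z <- ci_trajectory((0:45) * 4, rep(0, 46))
  fz <- ci_features(z)
  expect_true(fz$undefined)
  expect_equal(fz$auc, 0)
  expect_true(is.na(fz$t_max))
  # ties: earlier maximum wins
  two <- ci_trajectory(0:5, c(0, 5, 5, 2, 0, 0))
  expect_equal(ci_features(two, adapt_fraction = 0.1)$t_max, 1)
  # counts never adapting: right-censored at the last timepoint
  flat <- ci_trajectory(0:5, c(0, 10, 10, 10, 10, 10))
  ff <- ci_features(flat, adapt_fraction = 0.1)
  expect_true(ff$right_censored)
  expect_equal(ff$t_adapt, 5)
})

test_that("Gaussian-sum fit recovers curves and handles degenerate traces", {
  tt <- (0:45) * 4
  truth <- list(a = c(30, 50, 20, 10), b = c(20, 45, 80, 120),
                c = c(12, 18, 25, 30))
  y <- eval_gaussian_sum(truth, tt)
  fit <- fit_gaussian_sum(ci_trajectory(tt, y))
  # curve recovery, not parameter recovery: the parameterization is redundant
  expect_lt(fit$sse, 1e-6 * sum(y^2))
  zero <- fit_gaussian_sum(ci_trajectory(tt, rep(0, 46)))
  expect_true(all(zero$a == 0))
  expect_equal(eval_gaussian_sum(zero, tt), rep(0, 46))
  tri <- make_triangular_ci(100, 100)
  tfit <- fit_gaussian_sum(tri)
  expect_lt(tfit$sse / sum(tri$counts^2), 0.05)
  on_grid <- eval_gaussian_sum(tfit, tt)
  expect_gt(min(on_grid), -1e-6 * max(tri$counts))
  # the t = 0 anchor holds the fitted curve near the (zero) initial count
  expect_lt(abs(eval_gaussian_sum(tfit, 0)), 0.02 * max(tri$counts))
  expect_error(fit_gaussian_sum(ci_trajectory(0:10, rep(1, 11))), "12 timepoints")
})

test_that("decay onset is the global maximum with first-on-ties and a responder gate", {
  tt <- 0:10
  rise_fall <- make_fc(tt, c(1, 1.2, 1.8, 2.5, 2.1, 1.7, 1.4, 1.2, 1.1, 1.05, 1))
  expect_equal(find_decay_onset(rise_fall), 4L)
  plateau <- make_fc(tt, c(1, 1.5, 2, 2, 1.8, 1.5, 1.3, 1.2, 1.1, 1.05, 1))
  expect_equal(find_decay_onset(plateau), 3L)
  flat <- make_fc(tt, rep(1, 11))
  onset <- find_decay_onset(flat)
  expect_true(is.na(onset))
  expect_true(attr(onset, "non_responder"))
})

test_that("export-order score separates exponential, linear and sub-floor decays", {
  tt <- seq(0, 180, by = 4)
  onset_val <- 2.5
  mk <- function(tail_fn) {
    fc <- c(1, 1.5, onset_val, tail_fn(tt[-(1:3)] - tt[3]))
    make_fc(tt, fc)
  }
  # genuine first-order decay, k well above the floor: exponential wins
  es_exp <- export_order_score(mk(function(t) onset_val * exp(-0.05 * t)))
  expect_lt(es_exp$sse_first, 1e-12)
  expect_lt(es_exp$score, 0)
  expect_equal(es_exp$order_class, "first")
  expect_equal(es_exp$k, 0.05, tolerance = 1e-3)
  # linear decay: the zero-order model is exact
  es_lin <- export_order_score(mk(function(t) onset_val - 0.01 * t))
  expect_lt(es_lin$sse_zero, 1e-18)
  expect_gt(es_lin$score, 0)
  expect_equal(es_lin$order_class, "zero")
  expect_equal(es_lin$m, -0.01, tolerance = 1e-6)
  # slower-than-floor exponential: the constrained exponential misfits, the
  # rate floor pins k, and the trace classifies as pseudo-zero-order
  es_slow <- export_order_score(mk(function(t) onset_val * exp(-0.001 * t)))
  expect_equal(es_slow$k, 0.0167)
  expect_gt(es_slow$sse_first, es_slow$sse_zero)
  expect_gt(es_slow$score, 0)
  expect_equal(es_slow$order_class, "zero")
  # N0 is pinned to the onset value
  expect_equal(es_exp$N0, onset_val)
  # non-responders and short tails are flagged undefined
  expect_true(export_order_score(make_fc(tt, rep(1, length(tt))))$undefined)
  short <- make_fc(0:3, c(1, 2, 1.5, 1.2))
  expect_true(export_order_score(short)$undefined)
})

test_that("export classification agrees with a brute-force two-model comparison", {
  # independent oracle: exhaustive k grid + closed-form linear fit
  brute_force_class <- function(t_rel, y) {
    X <- cbind(1, t_rel)
    beta <- solve(crossprod(X), crossprod(X, y))
    sse_zero <- sum((y - X %*% beta)^2)
    ks <- seq(0.0167, 10, length.out = 40000)
    sse_first <- min(vapply(ks, function(k) sum((y - y[1] * exp(-k * t_rel))^2),
                            numeric(1)))
    if (sse_first - sse_zero > 0) "zero" else "first"
  }
  set.seed(42)
  tt <- seq(0, 180, by = 4)
  n_each <- 50
  agree <- 0L
  for (i in seq_len(2 * n_each)) {
    exponential <- i <= n_each
    onset_val <- runif(1, 2, 3.5)
    tail_t <- tt[-(1:3)] - tt[3]
    y_tail <- if (exponential) {
      onset_val * exp(-runif(1, 0.02, 0.1) * tail_t)
    } else {
      pmax(onset_val - runif(1, 0.004, 0.012) * tail_t, 0)
    }
    y_tail <- pmax(y_tail + rnorm(length(y_tail), 0, 0.02), 0)
    traj <- make_fc(tt, c(1, 1.5, onset_val, y_tail))
    es <- export_order_score(traj)
    onset <- es$onset_index
    truth_class <- brute_force_class(tt[onset:length(tt)] - tt[onset],
                                     traj$fold_change[onset:length(tt)])
    agree <- agree + (es$order_class == truth_class)
  }
  expect_equal(agree, 2L * n_each)
})

test_that("elbow threshold finds the knee and is scale invariant", {
  # piecewise SSE population with a sharp knee: many small, few large
  sses <- c(seq(0.1, 1, length.out = 40), seq(5, 50, length.out = 8))
  elbow <- elbow_threshold(sses)
  # independent brute force over all candidates
  s <- sort(unique(sses))
  n_above <- vapply(s, function(th) sum(sses > th), numeric(1))
  x <- (s - min(s)) / diff(range(s))
  y <- (n_above - min(n_above)) / diff(range(n_above))
  d <- abs((y[length(y)] - y[1]) * (x - x[1]) - (x[length(x)] - x[1]) * (y - y[1]))
  expect_equal(elbow, s[which.max(d)])
  expect_equal(elbow_threshold(10 * sses), 10 * elbow)
  expect_identical(which(s == elbow), which(10 * s == elbow_threshold(10 * sses)))
  expect_error(elbow_threshold(c(1, 1, 1)), "3 distinct")
  expect_warning(deg <- elbow_threshold(1:10), "degenerate")
  expect_equal(as.numeric(deg), 1)
})

test_that("fit-quality classification is an inclusive-boundary partition", {
  sse <- c(a = 1, b = 2, c = 2.0001, d = 4, e = 4.0001, f = 9)
  rep <- classify_fits(sse, elbow = 4)
  expect_equal(rep$excellent_threshold, 2)
  expect_equal(unname(rep$labels[c("a", "b")]), c("excellent", "excellent"))
  expect_equal(unname(rep$labels[c("c", "d")]), c("high", "high"))
  expect_equal(unname(rep$labels[c("e", "f")]), c("low", "low"))
  expect_equal(sum(rep$counts), length(sse))
  all_low <- classify_fits(c(x = 0.1, y = 0.2), elbow = 1)
  expect_true(all(all_low$labels == "excellent"))
  expect_error(classify_fits(sse, elbow = 0), "> 0")
})

test_that("feature tables summarize a cohort end to end", {
  coh <- small_cohort()
  tab <- feature_table(coh$ci_trajectories, coh$nfkb_trajectories)
  expect_equal(nrow(tab), length(coh$ci_trajectories))
  expect_true(all(c("auc_nfkb", "auc_ci", "t_max", "t_adapt",
                    "export_score", "order_class") %in% names(tab)))
  expect_true(all(tab$auc_nfkb >= 0))
  med <- tapply(tab$auc_nfkb, tab$condition, median)
  expect_gt(med[["4x1.5"]] / med[["1x6"]], 1.5)
})
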