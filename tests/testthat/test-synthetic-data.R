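test_that("triangular CI generator produces the requested geometry", {
  tri <- make_triangular_ci(100, 100, smooth_window = 1)
  expect_equal(length(tri$times), 46)
  expect_equal(diff(tri$times)[1], 4)
  # peak at 28 min, which is index position 7 counting from zero
  expect_equal(which.max(tri$counts), 8L)
  expect_equal(tri$times[which.max(tri$counts)], 28)
  expect_equal(max(tri$counts), 100)
  # linear rise and fall, zero after adaptation
  expect_equal(tri$counts[tri$times == 16], 100 * 16 / 28)
  expect_equal(tri$counts[tri$times == 64], 100 * (100 - 64) / 72)
  expect_true(all(tri$counts[tri$times >= 100] == 0))
  expect_true(all(tri$counts >= 0))
})

test_that("triangle generator rejects invalid geometry and snaps peak times", {
  expect_error(make_triangular_ci(0, 60), "peak_height")
  expect_error(make_triangular_ci(-5, 60), "peak_height")
  expect_error(make_triangular_ci(100, 20, peak_time = 28), "geometry")
  expect_error(make_triangular_ci(100, 28, peak_time = 28), "geometry")
  snapped <- make_triangular_ci(100, 80, peak_time = 27)
  expect_equal(snapped$meta$peak_time, 28)
  expect_equal(unname(snapped$meta$peak_time_snapped["from"]), 27)
  # bounds: unit peak stays in [0, 1] through smoothing
  small <- make_triangular_ci(1, 32)
  expect_true(all(small$counts >= 0 & small$counts <= 1))
})

test_that("smoothing is identity at window 1 and AUC-preserving at window 3", {
  for (ph in c(30, 100, 250)) {
    for (ad in c(40, 100, 160)) {
      raw <- make_triangular_ci(ph, ad, smooth_window = 1)
      sm <- make_triangular_ci(ph, ad, smooth_window = 3)
      auc_raw <- pracma::trapz(raw$times, raw$counts)
      # discrete AUC of the raw triangle matches the analytic area to within
      # one grid cell of discretization error
      expect_lt(abs(auc_raw - ph * ad / 2), ph * 4)
      # smoothing preserves nonnegativity and moves AUC by < 5%
      expect_true(all(sm$counts >= 0))
      auc_sm <- pracma::trapz(sm$times, sm$counts)
      expect_lt(abs(auc_sm - auc_raw) / auc_raw, 0.05)
    }
  }
  tri1 <- make_triangular_ci(77, 88, smooth_window = 1)
  expect_identical(tri1$counts, tri1$meta$raw_counts)
})

test_that("pulse-condition library matches its documented design", {
  lib <- pulse_library()
  expect_true(all(c("control", "1x6", "2x3", "3x2", "4x1.5", "1x15", "1x30")
                  %in% names(lib)))
  for (tpl in lib) {
    expect_equal(length(tpl$times), 46)
    expect_equal(diff(tpl$times)[1], 4)
  }
  expect_true(all(lib$control$counts == 0))
  # equal-exposure split pulses: comparable CI area, much longer adaptation
  f6 <- ci_features(lib[["1x6"]])
  f45 <- ci_features(lib[["4x1.5"]])
  expect_lt(abs(f45$auc - f6$auc) / f6$auc, 0.10)
  expect_gt(f45$t_adapt - f6$t_adapt, 40)
  # adaptation time from the generator is ordered across the split series
  ts <- vapply(lib[c("1x6", "2x3", "3x2", "4x1.5")],
               function(x) ci_features(x)$t_adapt, numeric(1))
  expect_true(all(diff(ts) > 0))
})

test_that("measured adaptation time is non-decreasing in the generator parameter", {
  t_adapts <- vapply(seq(48, 168, by = 24), function(ad) {
    ci_features(make_triangular_ci(100, ad))$t_adapt
  }, numeric(1))
  expect_true(all(diff(t_adapts) >= 0))
})

test_that("cohort generation is seed-deterministic and respects noise settings", {
  p <- gt_params()
  lib <- pulse_library()
  c1 <- generate_cohort(p, lib["1x6"], n_cells_per_condition = 3,
                        ci_jitter = 0.08, noise_sd = 0.04, seed = 11)
  c2 <- generate_cohort(p, lib["1x6"], n_cells_per_condition = 3,
                        ci_jitter = 0.08, noise_sd = 0.04, seed = 11)
  expect_identical(lapply(c1$nfkb_trajectories, `[[`, "fold_change"),
                   lapply(c2$nfkb_trajectories, `[[`, "fold_change"))
  expect_identical(lapply(c1$ci_trajectories, `[[`, "counts"),
                   lapply(c2$ci_trajectories, `[[`, "counts"))
  c3 <- generate_cohort(p, lib["1x6"], n_cells_per_condition = 3,
                        ci_jitter = 0.08, noise_sd = 0.04, seed = 12)
  expect_false(identical(lapply(c1$nfkb_trajectories, `[[`, "fold_change"),
                         lapply(c3$nfkb_trajectories, `[[`, "fold_change")))
  # degenerate noise: every cell equals the condition-average simulation
  c0 <- generate_cohort(p, lib["1x6"], n_cells_per_condition = 3,
                        ci_jitter = 0, noise_sd = 0, seed = 5)
  fc <- vapply(c0$nfkb_trajectories, `[[`, numeric(46), "fold_change")
  expect_lt(max(abs(fc - fc[, 1])), 1e-12)
  ref <- gt_condition_sims()[["1x6"]]$fold_change
  expect_lt(max(abs(fc[, 1] - ref)), 1e-6)
  # every trajectory is a valid fold change
  expect_true(all(vapply(c1$nfkb_trajectories,
                         function(x) x$fold_change[1] == 1, logical(1))))
})

test_that("noisy cohort means concentrate on the noiseless simulation (CLT)", {
  p <- gt_params()
  lib <- pulse_library()
  noise_sd <- 0.05
  n <- 20
  coh <- generate_cohort(p, lib["1x6"], n_cells_per_condition = n,
                         ci_jitter = 0, noise_sd = noise_sd, seed = 21)
  fc <- vapply(coh$nfkb_trajectories, `[[`, numeric(46), "fold_change")
  ref <- gt_condition_sims()[["1x6"]]$fold_change
  dev <- abs(rowMeans(fc) - ref)[-1]     # t = 0 is pinned at 1 by design
  expect_true(all(dev < 2 * noise_sd / sqrt(n) + 0.01))
})

test_that("cohort CSV round trip is lossless", {
  coh <- generate_cohort(gt_params(), pulse_library()[c("1x6", "control")],
                         n_cells_per_condition = 2, ci_jitter = 0.1,
                         noise_sd = 0.03, seed = 33)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(length(back$ci_trajectories), length(coh$ci_trajectories))
  expect_equal(lapply(back$nfkb_trajectories, `[[`, "fold_change"),
               lapply(coh$nfkb_trajectories, `[[`, "fold_change"),
               tolerance = 1e-12)
  expect_equal(back$seed, coh$seed)
  expect_equal(back$ground_truth$ka1d, coh$ground_truth$ka1d)
})

test_that("trajectory tables read from Gaussian-parameter and count layouts", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(cond = "1x6", cell = "c1",
                   a1 = 50, a2 = 0, a3 = 0, a4 = 0,
                   b1 = 30, b2 = 60, b3 = 90, b4 = 120,
                   c1 = 15, c2 = 10, c3 = 10, c4 = 10)
  write.csv(df, path, row.names = FALSE)
  fits <- read_ikk_trajectory_table(path, layout = list(
    condition_col = "cond", cell_col = "cell",
    gaussian_cols = c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4",
                      "c1", "c2", "c3", "c4")))
  expect_equal(length(fits), 1)
  expect_equal(eval_gaussian_sum(fits[[1]], 30), 50)
  path2 <- withr::local_tempfile(fileext = ".csv")
  counts <- data.frame(cond = "x", cell = "c2", t0 = 0, t1 = 5, t2 = 3)
  write.csv(counts, path2, row.names = FALSE)
  cis <- read_ikk_trajectory_table(path2, layout = list(
    condition_col = "cond", cell_col = "cell",
    count_cols = c("t0", "t1", "t2"), times = c(0, 4, 8)))
  expect_s3_class(cis[[1]], "ci_trajectory")
  expect_equal(cis[[1]]$counts, c(0, 5, 3))
})
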