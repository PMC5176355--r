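test_that("Gompertz fit recovers noiseless growth parameters exactly", {
  gc <- gen_growth_curves(mu = 0.6, lag = 1, amplitude = 2, noise_cv = 0,
                          seed = 1)
  fit <- fit_growth_curve(gc$time, gc$od600)
  expect_lt(rel_diff(fit$mu_max, 0.6), 1e-8)
  expect_lt(abs(fit$lag - 1), 1e-8)
  expect_lt(rel_diff(fit$amplitude, 2), 1e-8)
  # constant OD is flat: mu = 0 with a warning
  expect_warning(flat <- fit_growth_curve(seq(0, 720, 15),
                                          rep(0.05, 49)), "flat")
  expect_identical(flat$mu_max, 0)
  expect_true(flat$flat)
})

test_that("growth-rate recovery holds across the physiological mu range", {
  # 1% multiplicative noise; median recovery within 2% for each mu
  for (mu in c(0.1, 0.6, 1.5)) {
    errs <- sapply(1:30, function(s) {
      g <- gen_growth_curves(mu = mu, lag = 1, amplitude = 2,
                             noise_cv = 0.01, seed = s)
      rel_diff(fit_growth_curve(g$time, g$od600)$mu_max, mu)
    })
    expect_lt(median(errs), 0.02)
  }
})

test_that("relative growth normalization behaves and flags bad references", {
  expect_identical(relative_growth(0.5, 0.5), 1)
  expect_identical(relative_growth(0, 0.5), 0)
  # a 73% reduction in growth rate maps to relative growth 0.27
  expect_equal(relative_growth(0.27, 1.0), 0.27)
  expect_error(relative_growth(0.5, 0), "mu_ref")
})

test_that("depletion branch fits the saturating abundance-fitness form", {
  fp <- gen_fitness_curve("depletion", params = list(fmax = 1, kf = 0.05),
                          n_points = 8, sd = 0, seed = 2)
  fit <- fit_depletion_branch(fp)
  expect_lt(rel_diff(fit$fmax, 1), 1e-6)
  expect_lt(rel_diff(fit$kf, 0.05), 1e-6)
  # half-fitness at the fitted Kf
  expect_equal(predict(fit, fit$kf), fit$fmax / 2, tolerance = 1e-12)
  expect_error(fit_depletion_branch(fp[1:3, ]), "4 depletion")
  # 3% noise recovery within 10% (median over seeds)
  kfs <- sapply(1:40, function(s) {
    f <- gen_fitness_curve("depletion",
                           params = list(fmax = 1, kf = 0.05),
                           n_points = 8, sd = 0.03, seed = s)
    fit_depletion_branch(f)$kf
  })
  expect_lt(rel_diff(median(kfs), 0.05), 0.10)
})

test_that("overexpression branch fits a decreasing sigmoid with usable predictions", {
  truth <- list(bottom = 0.25, top = 1, mid = 40, hill = 1.5)
  fp <- gen_fitness_curve("overexpression", params = truth,
                          n_points = 8, sd = 0, seed = 3)
  fit <- fit_overexpression_branch(fp)
  expect_lt(rel_diff(fit$mid, truth$mid), 1e-5)
  expect_lt(rel_diff(fit$hill, truth$hill), 1e-5)
  # prediction at the fitted midpoint abundance is the half-way fitness
  expect_equal(predict(fit, fit$mid), (fit$top + fit$bottom) / 2,
               tolerance = 1e-10)
  # an increasing series triggers the trend warning
  up <- fitness_points(c(1, 5, 25, 125, 625), c(0.2, 0.4, 0.6, 0.8, 1))
  expect_warning(fit_overexpression_branch(up), "increases")
})

test_that("a strictly decreasing overexpression series has rho = -1", {
  fp <- gen_fitness_curve("overexpression", n_points = 6, sd = 0,
                          seed = 4)
  rc <- rank_correlation(fp)
  expect_identical(rc$rho, -1)
})

test_that("ortholog significance flags departures from the fitted curve", {
  fp <- gen_fitness_curve("overexpression", n_points = 8, sd = 0,
                          seed = 5)
  fit <- fit_overexpression_branch(fp)
  pred <- predict(fit, 50)
  # replicates exactly at the prediction: p = 1
  res0 <- ortholog_significance(fit, 50, rep(pred, 3))
  expect_equal(res0$p_value, 1)
  # replicates 20 assigned SDs above the prediction: p < 0.001
  res1 <- ortholog_significance(fit, 50,
                                rep(pred * (1 + 20 * 0.03), 3) *
                                  c(0.999, 1, 1.001))
  expect_lt(res1$p_value, 0.001)
  # the deterministic expected side carries the assigned 3% SD
  expect_equal(sd(res0$expected_reps), 0.03 * pred, tolerance = 1e-12)
  expect_warning(ortholog_significance(fit, 1e4, rep(pred, 3)),
                 "extrapolation")
  expect_error(ortholog_significance(fit, 50, rep(pred, 2)),
               "3 ortholog")
})

test_that("rescue factor is the interaction-corrected growth gain", {
  expect_identical(rescue_factor(0.5, 0.5, 0.9, 0.9), 0)
  expect_equal(rescue_factor(0.50, 0.40, 0.95, 1.00), 0.15)
  # partner toxic but no interaction: pure toxicity correction
  expect_equal(rescue_factor(0.40, 0.40, 0.90, 1.00), 0.10)
  # invariant under adding a constant to all four rates
  expect_equal(rescue_factor(0.50 + 0.2, 0.40 + 0.2, 0.95 + 0.2,
                             1.00 + 0.2),
               rescue_factor(0.50, 0.40, 0.95, 1.00))
})

test_that("Spearman permutation p-values are exact for small n", {
  # five strictly decreasing points: the reversal is one of 2 extreme
  # orderings among 5! = 120, so two-sided p = 2/120
  rc5 <- rank_correlation(1:5, 5:1)
  expect_identical(rc5$rho, -1)
  expect_equal(rc5$p_value, 2 / 120, tolerance = 1e-12)
  expect_equal(rank_correlation(1:5, 5:1,
                                alternative = "less")$p_value, 1 / 120,
               tolerance = 1e-12)
  # six points: 2/720 two-sided
  expect_equal(rank_correlation(1:6, 6:1)$p_value, 2 / 720,
               tolerance = 1e-12)
  # degenerate constant input
  expect_warning(rc_const <- rank_correlation(1:5, rep(1, 5)),
                 "constant")
  expect_true(is.na(rc_const$rho))
})

test_that("permutation null p-values are uniform under exchangeability", {
  set.seed(77)
  ps <- replicate(400, rank_correlation(1:6, sample(6))$p_value)
  # discrete-uniform null: mean 0.5-ish and calibrated tail mass
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.58)
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 0.03)
})
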