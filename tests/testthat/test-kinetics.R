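test_that("Michaelis-Menten fit recovers parameters and identities", {
  d <- gen_mm_dataset(kcat = 10, km = 1e-6, enzyme_conc = 1e-8,
                      noise_cv = 0, seed = 1)
  fit <- fit_michaelis_menten(d)
  expect_lt(rel_diff(fit$km, 1e-6), 1e-9)
  expect_lt(rel_diff(fit$kcat, 10), 1e-9)
  # efficiency is exactly kcat / km
  expect_identical(fit$efficiency, fit$kcat / fit$km)
  # half-saturation on the fitted curve
  expect_equal(predict(fit, fit$km), fit$vmax / 2, tolerance = 1e-12)
  expect_false(fit$span_warning)
  expect_error(
    fit_michaelis_menten(rate_dataset(dhf_conc_grid(),
                                      rep(0, 8), 1e-8)),
    "zero")
})

test_that("MM fit agrees with the Lineweaver-Burk closed form on exact data", {
  # two exact points determine (Vmax, KM) by the double-reciprocal lines;
  # the nonlinear fit on richer exact data must land on the same pair
  vmax <- 2e-7
  km <- 5e-5
  s2 <- c(2e-5, 2e-4)
  v2 <- vmax * s2 / (km + s2)
  # closed form from 1/v = 1/Vmax + (KM/Vmax) / S
  slope <- diff(1 / v2) / diff(1 / s2)
  inter <- 1 / v2[1L] - slope / s2[1L]
  vmax_lb <- 1 / inter
  km_lb <- slope * vmax_lb
  d <- rate_dataset(thf_conc_grid(), vmax * thf_conc_grid() /
                      (km + thf_conc_grid()), enzyme_conc = 2.5e-7)
  fit <- fit_michaelis_menten(d)
  expect_lt(rel_diff(fit$vmax, vmax_lb), 1e-8)
  expect_lt(rel_diff(fit$km, km_lb), 1e-8)
})

test_that("a substrate grid that misses KM raises the span warning", {
  s <- c(10, 20, 40, 80) * 1e-6
  d <- rate_dataset(s, 1e-7 * s / (1e-6 + s), enzyme_conc = 1e-8)
  expect_warning(fit <- fit_michaelis_menten(d), "bracket")
  expect_true(fit$span_warning)
})

test_that("modulation profile normalizes against the no-modulator reference", {
  ref <- fit_michaelis_menten(gen_mm_dataset(kcat = 10, km = 1e-6,
                                             enzyme_conc = 1e-8,
                                             noise_cv = 0, seed = 1))
  # KM doubles per modulator step, kcat unchanged
  fits <- lapply(1:4, function(i) {
    suppressWarnings(   # 16 uM KM sits on the grid edge
      fit_michaelis_menten(gen_mm_dataset(kcat = 10, km = 1e-6 * 2^i,
                                          enzyme_conc = 1e-8,
                                          noise_cv = 0, seed = i,
                                          modulator_name = "EcDHFR",
                                          modulator_conc = i * 1e-6)))
  })
  prof <- modulation_profile(fits, ref)
  expect_equal(prof$km_ratio, c(2, 4, 8, 16), tolerance = 1e-8)
  expect_equal(prof$kcat_ratio, rep(1, 4), tolerance = 1e-8)
  # identical fit -> unity ratios
  prof0 <- modulation_profile(list(ref), ref)
  expect_equal(prof0$km_ratio, 1, tolerance = 1e-12)
  # monotone KM trend is detected by a rank test
  expect_identical(rank_correlation(prof$modulator_conc,
                                    prof$km_ratio,
                                    alternative = "greater")$rho, 1)
  # mismatched enzymes and a non-zero reference are rejected
  other <- fit_michaelis_menten(gen_mm_dataset(seed = 5,
                                               enzyme_name = "other"))
  expect_error(modulation_profile(list(other), ref), "same enzyme")
  expect_error(modulation_profile(list(ref), fits[[1L]]),
               "without modulator")
})

test_that("IC50 fit recovers an exact 4PL and its midpoint identity", {
  x <- c(0, 0.5, 1, 2, 3, 5, 10, 30, 100)
  y <- 0.2 + (1.0 - 0.2) / (1 + (x / 3)^2)
  fit <- fit_ic50(x, y)
  expect_lt(rel_diff(fit$ic50, 3), 1e-6)
  expect_lt(rel_diff(fit$hill, 2), 1e-6)
  expect_equal(fit$bottom, 0.2, tolerance = 1e-6)
  expect_equal(fit$top, 1.0, tolerance = 1e-6)
  # y at the fitted IC50 is exactly the midpoint
  expect_equal(predict(fit, fit$ic50), (fit$top + fit$bottom) / 2,
               tolerance = 1e-12)
  expect_error(fit_ic50(x[1:4], y[1:4]), "5 points")
})

test_that("IC50 fit is equivariant under uniform signal rescaling", {
  x <- c(0, 0.5, 1, 2, 3, 5, 10, 30, 100)
  set.seed(3)
  y <- (0.2 + 0.8 / (1 + (x / 3)^1.5)) * (1 + 0.02 * rnorm(length(x)))
  f1 <- fit_ic50(x, y)
  f2 <- fit_ic50(x, 10 * y)
  expect_equal(f2$ic50, f1$ic50, tolerance = 1e-6)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
  expect_equal(f2$bottom, 10 * f1$bottom, tolerance = 1e-6)
  expect_equal(f2$top, 10 * f1$top, tolerance = 1e-6)
})

test_that("ligand saturation fit recovers Amax and KD", {
  L <- c(0, 5, 10, 25, 50, 100, 250, 500, 1000) * 1e-6
  A <- 0.5 * L / (L + 5e-5)
  fit <- fit_saturation_kd(L, A)
  expect_lt(rel_diff(fit$kd_ligand, 5e-5), 1e-6)
  expect_lt(rel_diff(fit$amax, 0.5), 1e-6)
  # a competitor that raises the apparent KD preserves the ordering
  set.seed(9)
  kds <- c(5e-5, 1.2e-4, 3e-4)  # buffer < weak competitor < strong
  rec <- sapply(kds, function(k) {
    sig <- (0.5 * L / (L + k)) * (1 + 0.02 * rnorm(length(L)))
    fit_saturation_kd(L, sig)$kd_ligand
  })
  expect_identical(order(rec), 1:3)
})
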