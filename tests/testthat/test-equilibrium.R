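test_that("pairwise solver matches the mass-action fixed-point oracle at basal abundances", {
  D <- 5e-8
  P <- 2e-7
  K <- 3e-6
  c_oracle <- pairwise_complex_oracle(D, P, K)
  st <- solve_pairwise(D, P, K, hub = "DHFR", partner = "PurH")
  expect_lt(rel_diff(st$complex[["PurH"]], c_oracle), 1e-9)
  # at KD = 3 uM exactly the complex is ~3.08e-9 M: 6.2% of the hub and
  # 1.5% of the partner are bound
  expect_equal(unname(st$complex), 3.08e-9, tolerance = 5e-3)
  expect_equal(100 * unname(st$fraction_bound["DHFR"]), 6.2,
               tolerance = 0.01)
  expect_equal(100 * unname(st$fraction_bound["PurH"]), 1.54,
               tolerance = 0.01)
  validate_equilibrium_state(st)
})

test_that("pairwise solver handles degenerate and limiting inputs", {
  # no partner: everything free
  st0 <- solve_pairwise(5e-8, 0, 3e-6)
  expect_identical(unname(st0$complex), 0)
  expect_identical(unname(st0$free[1L]), 5e-8)
  # very weak binding: bound fractions vanish
  stw <- solve_pairwise(1e-6, 1e-6, 1)
  expect_lt(max(stw$fraction_bound), 1e-4)
  # negative input is a domain error
  expect_error(solve_pairwise(-1e-9, 1e-7, 3e-6), "hub_total")
  expect_error(solve_pairwise(1e-9, 1e-7, 0), "kd")
})

test_that("quadratic root selection is numerically stable when 4DP << b^2", {
  # trace amounts against a huge KD: naive root subtraction would lose all
  # precision; the complex must still match D*P/K to first order
  D <- 1e-12
  P <- 1e-12
  K <- 1
  st <- solve_pairwise(D, P, K)
  expect_lt(rel_diff(unname(st$complex), D * P / K), 1e-6)
  expect_gt(unname(st$complex), 0)
})

test_that("competitive solver reduces to the pairwise quadratic for one partner", {
  sys <- equilibrium_system("DHFR", 5e-8, "PurH", 2e-7, kds = 3e-6)
  stc <- solve_competitive(sys)
  stp <- solve_pairwise(5e-8, 2e-7, 3e-6, hub = "DHFR", partner = "PurH")
  expect_lt(rel_diff(stc$free[["DHFR"]], stp$free[["DHFR"]]), 1e-9)
  expect_lt(rel_diff(stc$free[["PurH"]], stp$free[["PurH"]]), 1e-9)
  validate_equilibrium_state(stc, sys)
})

test_that("competitive solver matches the fixed-point oracle on small systems", {
  # two identical partners against a scarce hub
  sys2 <- equilibrium_system("hub", 5e-8, c("a", "b"), c(2e-7, 2e-7),
                             kds = c(3e-6, 3e-6))
  st2 <- solve_competitive(sys2)
  h_or <- competitive_free_hub_oracle(5e-8, c(2e-7, 2e-7), c(3e-6, 3e-6))
  expect_lt(rel_diff(st2$free[["hub"]], h_or), 1e-9)
  validate_equilibrium_state(st2, sys2)
  # hub absent: partners fully free
  sys0 <- equilibrium_system("hub", 0, "a", 2e-7, kds = 3e-6)
  st0 <- solve_competitive(sys0)
  expect_identical(st0$free[["a"]], 2e-7)
  # no partners: hub fully free
  sysn <- equilibrium_system("hub", 5e-8)
  expect_identical(solve_competitive(sysn)$free[["hub"]], 5e-8)
})

test_that("mass conservation and monotone sequestration hold over random systems", {
  set.seed(4021)
  for (i in 1:25) {
    sys <- random_system(sample(1:3, 1))
    st <- solve_competitive(sys)
    validate_equilibrium_state(st, sys, tol = 1e-9)
    # bound fraction of each partner grows with hub total
    scans <- titration_scan(sys, c(1, 5, 25, 125))
    for (p in sys$partners$name) {
      fb <- scans$fraction_bound[scans$species == p]
      expect_true(all(diff(fb) >= -1e-12))
    }
  }
})

test_that("trace partners approach the closed-form saturation fraction", {
  # P << K and P << H: partner bound fraction -> H / (H + K)
  H <- 1e-5
  K <- 3e-6
  P <- 1e-10
  st <- solve_pairwise(H, P, K)
  expect_equal(unname(st$fraction_bound[2L]), H / (H + K),
               tolerance = 1e-2)
})

test_that("titration scan reproduces the overexpression sequestration regime", {
  sys <- equilibrium_system("DHFR", 5e-8, "PurH", 2e-7, kds = 3e-6)
  sc <- titration_scan(sys, c(1, 1000))
  # fold = 1 reproduces the basal pairwise state
  basal <- solve_pairwise(5e-8, 2e-7, 3e-6)
  expect_equal(sc$fraction_bound[sc$fold == 1 & sc$species == "PurH"],
               unname(basal$fraction_bound[2L]), tolerance = 1e-9)
  # at 1000-fold the free partner fraction approaches K / (K + H)
  free_frac <- 1 - sc$fraction_bound[sc$fold == 1000 &
                                       sc$species == "PurH"]
  expect_equal(free_frac, 3e-6 / (3e-6 + 5e-5), tolerance = 2e-2)
  # empty factor list gives an empty table with the same columns
  empty <- titration_scan(sys, numeric())
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(sc))
})

test_that("copy-number / molar conversions reproduce the cited cell volume", {
  expect_equal(copies_to_molar(50), 5e-8, tolerance = 1e-3)
  expect_equal(copies_to_molar(200), 2e-7, tolerance = 1e-3)
  expect_identical(copies_to_molar(0), 0)
  expect_equal(molar_to_copies(copies_to_molar(123)), 123,
               tolerance = 1e-12)
  expect_error(copies_to_molar(10, cell_volume = 0), "cell_volume")
})
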