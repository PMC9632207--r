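test_that("region split at the default boundary halves a uniform grid and rejects degenerate cuts", {
  ser <- new_series_for_test(seq(1, 30))  # uniform xB grid 1/30 .. 1
  parts <- split_regions(ser, 0.5)
  expect_identical(nrow(parts$low), 15L)
  expect_identical(nrow(parts$high), 15L)
  expect_true(all(parts$low$ligand_uM <= 15))
  expect_error(split_regions(ser, 0.99), "degenerate")
  expect_error(split_regions(ser, 1.0), "strictly inside")
})

test_that("Hill prediction equals half-saturation at L = Kd for any n", {
  for (n in c(0.5, 1, 1.37, 3.25, 6)) {
    Ka <- 5.65e7
    Kd_uM <- 1e6 / Ka
    ser <- simulate_hill_series(hill_grid_uM(Ka), n, Ka, q_max = 30)
    fit <- fit_hill(ser)
    expect_equal(predict(fit, 1e6 * fit$Kd), fit$q_max / 2,
                 tolerance = 1e-8)
  }
})

test_that("zero-noise Hill refits recover the low- and high-region truths", {
  low <- hill_truth_low
  ser_lo <- simulate_hill_series(hill_grid_uM(low$Ka), low$n, low$Ka,
                                 q_max = 30)
  fit_lo <- fit_hill(ser_lo, region = "low")
  expect_lt(rel_err(fit_lo$n, low$n), 1e-4)
  expect_lt(rel_err(fit_lo$Ka, low$Ka), 1e-4)
  expect_identical(classify_cooperativity(fit_lo$n), "positive")

  high <- hill_truth_high
  ser_hi <- simulate_hill_series(hill_grid_uM(high$Ka), high$n, high$Ka,
                                 q_max = 30)
  fit_hi <- fit_hill(ser_hi, region = "high")
  expect_lt(rel_err(fit_hi$n, high$n), 1e-4)
  expect_lt(rel_err(fit_hi$Ka, high$Ka), 1e-4)
})

test_that("n = 1 data reduce to the one-site hyperbola and agree with a direct one-site fit", {
  Ka <- 1e6
  ser <- simulate_hill_series(hill_grid_uM(Ka), 1, Ka, q_max = 20)
  fit <- fit_hill(ser)
  expect_lt(abs(fit$n - 1), 1e-5)
  # independent one-site fit (Kd, qmax) via nls on the same data
  L <- ser$ligand_uM * 1e-6
  one <- stats::nls(heat ~ qmax * L / (Kd + L),
                    data = data.frame(heat = ser$heat, L = L),
                    start = list(qmax = max(ser$heat), Kd = median(L)),
                    algorithm = "port")
  expect_lt(rel_err(fit$Ka, 1 / coef(one)[["Kd"]]), 1e-4)
})

test_that("two-region analysis of a region-dependent truth yields distinct coefficients", {
  low <- hill_truth_low; high <- hill_truth_high
  grid_lo <- hill_grid_uM(low$Ka, span = 10)
  grid_hi <- hill_grid_uM(high$Ka, span = 10)
  ser_lo <- simulate_hill_series(grid_lo, low$n, low$Ka, q_max = 30)
  ser_hi <- simulate_hill_series(grid_hi, high$n, high$Ka, q_max = 30)
  f_lo <- fit_hill(ser_lo, "low"); f_hi <- fit_hill(ser_hi, "high")
  expect_gt(abs(f_lo$n - f_hi$n), 1)
  expect_true(f_lo$n > 1 && f_hi$n > 1)
})

test_that("per-region thermodynamics respect TdS = dH - dG and the low-region consistency", {
  # the low-concentration parameter row is internally consistent:
  # TdS = dH - dG = 4.52 - (-44.62) = 49.14, printed as 49.15
  th <- thermodynamics(hill_truth_low$Ka, hill_truth_low$dH, 300)
  expect_equal(th$TdS, th$dH - th$dG)
  expect_lt(abs((hill_truth_low$dH - hill_truth_low$dG) - hill_truth_low$TdS), 0.011)
  expect_lt(abs(th$dG - hill_truth_low$dG) / abs(hill_truth_low$dG), 0.005)
})

test_that("cooperativity classification bands behave at and around 1", {
  expect_identical(classify_cooperativity(1.37), "positive")
  expect_identical(classify_cooperativity(1.0), "non-cooperative")
  expect_identical(classify_cooperativity(0.5), "negative")
  expect_identical(classify_cooperativity(1.04), "non-cooperative")
  expect_identical(classify_cooperativity(1.2, epsilon = 0.3),
                   "non-cooperative")
  expect_error(classify_cooperativity(-1))
})
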