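test_that("mole fractions are complementary and reach 1 at the final injection", {
  ser <- canonical_titration()
  mf <- mole_fractions(ser)
  expect_equal(mf$xA + mf$xB, rep(1, nrow(ser)))
  expect_equal(mf$xB[nrow(ser)], 1)
  expect_true(all(diff(mf$xB) > 0))
  expect_equal(mole_fractions(c(5, 10))$xB, c(0.5, 1))
  expect_error(mole_fractions(c(0, 0)), "zero")
})

test_that("cooperative fraction: identity at p = 1, exact value at p = 1.2, endpoint preservation", {
  xB <- seq(0, 1, by = 0.05)
  expect_equal(cooperative_fraction(xB, 1), xB)
  expect_equal(cooperative_fraction(0.5, 1.2), 0.6 / 1.1)
  expect_equal(cooperative_fraction(c(0, 1), 3.7), c(0, 1))
  expect_error(cooperative_fraction(0.5, 0), "p must be")
})

test_that("cooperative fraction is strictly increasing in p on (0,1)", {
  xB <- seq(0.05, 0.95, by = 0.05)
  ps <- c(0.2, 0.5, 0.9, 1, 1.5, 3, 8)
  for (x in xB) {
    vals <- vapply(ps, function(p) cooperative_fraction(x, p), numeric(1))
    expect_true(all(diff(vals) > 0))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("predict_heats matches an independent elementwise evaluation", {
  # brute-force oracle written against the model definition, point by point
  oracle <- function(p, qmax, dA, dB, xB, LA, LB) {
    out <- numeric(length(xB))
    for (i in seq_along(xB)) {
      xbp <- p * xB[i] / ((1 - xB[i]) + p * xB[i])
      xap <- 1 - xbp
      out[i] <- qmax * xbp - (dA * xap + dB * xbp) * (xap * LA[i] + xbp * LB[i])
    }
    out
  }
  set.seed(2024)
  for (rep in 1:5) {
    p <- runif(1, 0.3, 4); qmax <- runif(1, -80, 80)
    dA <- runif(1, -1, 1); dB <- runif(1, -1, 1)
    xB <- sort(runif(7))
    LA <- runif(7, -5, 5); LB <- runif(7, -5, 5)
    params <- solvation_parameters(p, qmax, dA, dB)
    expect_equal(predict_heats(params, xB, LA, LB),
                 oracle(p, qmax, dA, dB, xB, LA, LB), tolerance = 1e-13)
  }
  # solvation terms vanish when the indices or dilution enthalpies are zero
  params <- solvation_parameters(1.4, 25, 0, 0)
  xB <- seq(0.1, 1, by = 0.1)
  xbp <- cooperative_fraction(xB, 1.4)
  expect_equal(predict_heats(params, xB, runif(10), runif(10)), 25 * xbp)
  params2 <- solvation_parameters(1.4, 25, -0.3, 0.2)
  expect_equal(predict_heats(params2, xB, 0, 0), 25 * xbp)
})

test_that("zero-noise refit recovers the canonical truth to optimizer tolerance", {
  truth <- canonical_solvation_truth()
  ser <- canonical_titration(truth = truth)
  fit <- fit_solvation(ser)
  expect_lt(max(rel_err(coef(fit), unlist(unclass(truth)))), 1e-6)
  expect_identical(classify_cooperativity(coef(fit)[["p"]]), "positive")
})

test_that("data with no solvation signal yield p = 1 and zero indices", {
  des <- titration_design()
  xB <- injection_schedule(des) / max(injection_schedule(des))
  ser <- simulate_titration(des, solvation_parameters(1, 40, 0, 0))
  fit <- fit_solvation(ser)
  expect_lt(abs(coef(fit)[["p"]] - 1), 1e-6)
  expect_identical(coef(fit)[["delta_A"]], 0)
  expect_identical(coef(fit)[["delta_B"]], 0)
  expect_true(fit$reduced)
})

test_that("random-truth recovery: 50 zero-noise parameter sets to <= 1e-4 relative", {
  set.seed(501)
  des <- titration_design()
  worst <- 0
  for (i in 1:50) {
    truth <- solvation_parameters(runif(1, 0.5, 5), runif(1, 10, 90),
                                  runif(1, -1, 1), runif(1, -1, 1))
    ser <- simulate_titration(des, truth,
                              dilution_coef = default_dilution_coef)
    fit <- fit_solvation(ser)
    err <- max(abs(coef(fit) - unlist(unclass(truth))) /
                 pmax(abs(unlist(unclass(truth))), 0.05))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-4)
})

test_that("partial molar dilution enthalpies follow the tangent construction", {
  g <- seq(0, 1, length.out = 21)
  # constant profile: zero derivative, LA = LB = c
  const <- partial_molar_dilution(simulate_dilution(g, 4.2))
  expect_equal(const$LA, rep(4.2, 21))
  expect_equal(const$LB, rep(4.2, 21))
  # linear profile: LA = a, LB = a + b everywhere
  lin <- partial_molar_dilution(simulate_dilution(g, c(1.5, -2)))
  expect_equal(lin$LA, rep(1.5, 21), tolerance = 1e-10)
  expect_equal(lin$LB, rep(1.5 - 2, 21), tolerance = 1e-10)
  # quadratic profile: central differences are exact for parabolas on a
  # uniform grid at interior points; ends are one-sided (first order)
  cf <- c(-2, 4, -3)
  quad <- partial_molar_dilution(simulate_dilution(g, cf))
  qd <- -2 + 4 * g - 3 * g^2
  dq_exact <- 4 - 6 * g
  interior <- 2:20
  expect_equal(quad$LA[interior], (qd - g * dq_exact)[interior],
               tolerance = 1e-10)
  expect_equal(quad$LB[interior], (qd + (1 - g) * dq_exact)[interior],
               tolerance = 1e-10)
  expect_error(partial_molar_dilution(simulate_dilution(c(0, 1), 1)),
               "3")
})

test_that("association constant estimator: algebraic fixed point and single-site oracle", {
  # constructed input: middle injection has xB' = 0.5 and Lfree = 1/K
  K <- 2e5  # L/mol
  L_mid_uM <- 1e6 / K
  ser <- new_series_for_test(c(L_mid_uM / 10, L_mid_uM, 2 * L_mid_uM),
                             enzyme_uM = 0)
  est <- association_constant(ser, solvation_parameters(1, 1, 0, 0),
                              window = c(0.4, 0.6))
  expect_equal(est$Ka, K, tolerance = 1e-10)

  # single-site regime: with p = Lmax/Kd and mid injections far below
  # Lmax, x'B tracks occupancy L/(Kd + L) and the estimator returns 1/Kd
  Kd_uM <- 10
  Lmax_uM <- 1e4
  grid <- c(seq(2, 90, length.out = 20), Lmax_uM)
  ser2 <- new_series_for_test(grid, enzyme_uM = 0)
  est2 <- association_constant(
    ser2, solvation_parameters(Lmax_uM / Kd_uM, 1, 0, 0))
  expect_lt(rel_err(est2$Ka, 1e6 / Kd_uM), 0.02)
})

test_that("thermodynamic identities: published-value consistency and exact round trips", {
  th <- thermodynamics(253009, 5.16, 300)
  expect_equal(round(th$dG, 2), -31.03)
  expect_equal(round(th$TdS, 2), 36.19)
  expect_equal(th$TdS, th$dH - th$dG)  # exact by construction
  expect_equal(thermodynamics(1, 7.7)$dG, 0)
  expect_equal(thermodynamics(1, 7.7)$TdS, 7.7)
  # inverse identity to 1e-12 relative
  for (Ka in c(1e-3, 1, 253009, 5.65e7, 2.46e8)) {
    back <- ka_from_energy(thermodynamics(Ka, 0)$dG)
    expect_lt(rel_err(back, Ka), 1e-12)
  }
  expect_error(thermodynamics(-1, 0), "positive")
})

test_that("noisy recovery: median relative error <= 10% at 2% noise over 100 seeds", {
  truth <- canonical_solvation_truth()
  scale <- max(abs(canonical_titration(truth = truth)$heat))
  errs <- matrix(NA_real_, 100, 4)
  for (s in 1:100) {
    ser <- canonical_titration(noise_sd = 0.02 * scale, seed = 3000 + s,
                               truth = truth)
    fit <- fit_solvation(ser)
    errs[s, ] <- rel_err(coef(fit), unlist(unclass(truth)))
  }
  expect_lte(median(errs), 0.10)
  # the cooperativity parameter and saturation heat are individually
  # well determined; the solvation indices sit at their information
  # limit under this design and are only constrained through the pooled
  # metric above
  expect_lte(median(errs[, 1]), 0.10)  # p
  expect_lte(median(errs[, 2]), 0.10)  # q_max
})
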