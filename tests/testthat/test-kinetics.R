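test_that("rate laws satisfy their defining algebraic identities", {
  S <- c(1, 3, 10, 30)
  v0 <- rate_law("noncompetitive", Vmax = 2, Km = 3, S = S, I = 0, Ki = 6)
  expect_equal(v0, rate_law("none", Vmax = 2, Km = 3, S = S))
  # I = Ki halves every noncompetitive velocity
  expect_equal(rate_law("noncompetitive", 2, 3, S, I = 6, Ki = 6), v0 / 2)
  # large-S limit tends to Vmax / (1 + I/Ki)
  expect_equal(rate_law("noncompetitive", 2, 3, S = 1e9, I = 3, Ki = 6),
               2 / 1.5, tolerance = 1e-8)
  expect_error(rate_law("ping-pong", 1, 1, 1))
})

test_that("Lineweaver-Burk lines share the x-intercept under noncompetitive inhibition", {
  ds <- noncomp_dataset(Km = 3)
  lb <- lineweaver_burk(ds)
  expect_identical(nrow(lb), 5L)
  expect_equal(lb$x_intercept, rep(-1 / 3, 5), tolerance = 1e-8)
  expect_equal(lb$Km_app, rep(3, 5), tolerance = 1e-8)
  expect_true(all(diff(lb$Vmax_app) < 0))
  expect_true(all(lb$r_squared > 1 - 1e-10))
})

test_that("Lineweaver-Burk lines share the y-intercept under competitive inhibition", {
  ds <- simulate_kinetics(kinetics_design(), "competitive",
                          Vmax = 1.5, Km = 3, Ki = 6.06)
  lb <- lineweaver_burk(ds)
  expect_equal(lb$intercept, rep(1 / 1.5, 5), tolerance = 1e-8)
  expect_true(all(diff(lb$Km_app) > 0))
})

test_that("mechanism classification is exact on noise-free grids of every mechanism", {
  des <- kinetics_design()
  cases <- list(noncompetitive = list(),
                competitive = list(),
                uncompetitive = list(),
                mixed = list(alpha = 3))
  for (mech in names(cases)) {
    alpha <- if (mech == "mixed") 3 else 1
    ds <- simulate_kinetics(des, mech, Vmax = 1, Km = 3, Ki = 6.06,
                            alpha = alpha)
    expect_identical(classify_mechanism(lineweaver_burk(ds)), mech)
  }
  ds_none <- simulate_kinetics(des, "none", Vmax = 1, Km = 3)
  expect_identical(classify_mechanism(lineweaver_burk(ds_none)), "none")
  one_level <- lineweaver_burk(noncomp_dataset())[1, ]
  expect_error(classify_mechanism(one_level), "at least 2")
})

test_that("global fit recovers Ki on zero-noise noncompetitive data and agrees with the secondary plot", {
  ds <- noncomp_dataset(Ki = 6.06)
  fit <- fit_inhibition(ds, "auto")
  expect_identical(fit$mechanism, "noncompetitive")
  expect_lt(rel_err(fit$Ki, 6.06), 1e-4)
  expect_lt(rel_err(fit$Vmax, 1), 1e-6)
  expect_lt(rel_err(fit$Km, 3), 1e-6)
  expect_lt(abs(fit$Ki - fit$Ki_secondary) / fit$Ki, 1e-6)
})

test_that("noisy Ki recovery: median relative error <= 10% at 5% noise over 100 seeds", {
  errs <- numeric(100)
  for (s in 1:100) {
    ds <- noncomp_dataset(Ki = 6.06, noise_sd = 0.05, seed = 6000 + s,
                          replicates = 3)
    ds$velocity <- pmax(ds$velocity, 1e-4)
    fit <- fit_inhibition(ds, "noncompetitive")
    errs[s] <- rel_err(fit$Ki, 6.06)
  }
  expect_lte(median(errs), 0.10)
})

test_that("the global fit is more precise than the double-reciprocal route on noisy data", {
  ki_g <- ki_s <- numeric(100)
  for (s in 1:100) {
    ds <- noncomp_dataset(Ki = 6.06, noise_sd = 0.03, seed = 9000 + s,
                          replicates = 2)
    ds$velocity <- pmax(ds$velocity, 1e-4)
    fit <- fit_inhibition(ds, "noncompetitive")
    ki_g[s] <- fit$Ki
    ki_s[s] <- fit$Ki_secondary
  }
  expect_lt(stats::mad(ki_g), stats::mad(ki_s))
})

test_that("IC50 logistic fit recovers truth and the IC50 = Ki identity holds for pure noncompetitive data", {
  dr <- simulate_dose_response(ic50_grid(), ic50 = 6.96, slope = 1)
  fit <- estimate_ic50(dr)
  expect_lt(rel_err(fit$ic50, 6.96), 1e-6)
  expect_lt(rel_err(fit$slope, 1), 1e-6)

  # fractional activity of a pure noncompetitive enzyme is
  # 1/(1 + I/Ki), so the fitted IC50 equals Ki
  Ki <- 6.06
  S <- 5
  I <- ic50_grid()
  v <- rate_law("noncompetitive", 1, 3, S = S, I = I, Ki = Ki)
  act <- v / rate_law("none", 1, 3, S = S)
  fit2 <- estimate_ic50(data.frame(inhibitor_uM = I, activity = act))
  expect_lt(rel_err(fit2$ic50, Ki), 1e-6)

  # symmetric grid about the IC50 recovers the slope exactly
  g <- 6.96 * exp(seq(-2, 2, length.out = 9))
  dr3 <- simulate_dose_response(g, 6.96, slope = 1.8)
  expect_lt(rel_err(estimate_ic50(dr3)$slope, 1.8), 1e-6)

  flat <- data.frame(inhibitor_uM = c(1, 2, 3), activity = c(.9, .88, .86))
  expect_error(estimate_ic50(flat), "0.5")
})

test_that("reversibility is read from enzyme-dilution intercepts", {
  E <- c(0.5, 1, 2, 4)
  Ki <- 6.06
  v <- sapply(c(0, 1, 5), function(I)
    E * 0.8 / (1 + I / Ki))  # v proportional to [E]: lines through origin
  chk <- reversibility_check(E, v)
  expect_true(chk$reversible)
  expect_true(all(abs(chk$intercepts) < 1e-12))
  v_off <- v
  v_off[, 2] <- v_off[, 2] + 0.1 * max(v)
  expect_false(reversibility_check(E, v_off)$reversible)
  expect_error(reversibility_check(c(1, 2), v[1:2, ]), "3")
})
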