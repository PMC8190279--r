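test_that("unit conversions follow the fixed internal unit system", {
  expect_equal(medium_concentration(0, 500), 0)
  expect_equal(medium_concentration(10, 530.14), 5.3014e6)
  expect_equal(medium_concentration(10, 1054.3), 1.05430e7)
  expect_error(medium_concentration(10, 0), class = "zfpk_invalid_input")

  expect_identical(dose_amount(2, 0.25), 0.5)
  expect_identical(dose_amount(0, 0.25), 0)
  expect_identical(dose_amount(4, 0.25), 1)
  expect_error(dose_amount(-1, 0.25), class = "zfpk_invalid_input")
})

test_that("closed-form amount matches hand evaluation and limits", {
  p <- cy3a_params(fluor = 1)
  inj <- exposure_regimen("PC", dose_mg_per_kg = 2)
  imm <- exposure_regimen("immersion", medium_conc_um = 10)

  # injection at t = 0 is exactly the injected amount (no absorption lag)
  expect_identical(amount_at_time(p, inj, 0), 0.5)
  # immersion tends to the steady state M*Q/ke
  ss <- steady_state_amount(p, imm, mw = 530.14)
  expect_equal(ss, 5.3014e6 * 8.37e-9 / 0.049)
  expect_equal(amount_at_time(p, imm, 1e5, mw = 530.14), ss, tolerance = 1e-12)
  # hand evaluation at 48 h: ss * (1 - exp(-ke*48))
  expect_equal(amount_at_time(p, imm, 48, mw = 530.14),
               0.90558 * (1 - exp(-2.352)), tolerance = 1e-3)
  # steady state is linear in M
  imm2 <- exposure_regimen("immersion", medium_conc_um = 20)
  expect_equal(steady_state_amount(p, imm2, mw = 530.14), 2 * ss)
  expect_error(steady_state_amount(p, inj, mw = 530.14),
               class = "zfpk_undefined_equilibrium")
})

test_that("fluorescence mapping is exactly linear in amount", {
  p <- pk_parameters(2000, 0.05, 1e-9)
  expect_identical(fluorescence(p, 0), 0)
  expect_identical(fluorescence(p, 0.5), 1000)
  expect_identical(fluorescence(pk_parameters(1, 0.05, 0), 3.7), 3.7)
})

test_that("ODE integration is an independent oracle for the closed form", {
  # pure decay reduces to a single exponential
  p <- pk_parameters(1, 0.1, 0)
  inj <- exposure_regimen("IP", dose_mg_per_kg = 2)
  tt <- c(0, 1, 5, 20, 48)
  traj <- amount_trajectory_ode(p, inj, tt)
  expect_equal(traj$amount_ng, 0.5 * exp(-0.1 * tt), tolerance = 1e-8)

  # uptake-only trajectory is nondecreasing and bounded by M*Q/ke
  p2 <- cy3a_params(1)
  imm <- exposure_regimen("immersion", medium_conc_um = 10)
  up <- amount_trajectory_ode(p2, imm, 0:48, mw = 530.14)$amount_ng
  expect_true(all(diff(up) > 0))
  expect_true(all(up <= steady_state_amount(p2, imm, mw = 530.14)))

  # 100 random parameter/regimen draws agree to < 1e-6 relative
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    p <- pk_parameters(fluor = runif(1, 1e3, 1e4),
                       ke = 10^runif(1, -2.5, -0.5),
                       q = 10^runif(1, -10, -8))
    rg <- exposure_regimen("combination",
                           medium_conc_um = runif(1, 1, 50),
                           dose_mg_per_kg = runif(1, 0.5, 5))
    mw <- runif(1, 300, 1100)
    tt <- sort(runif(6, 0, 48))
    a_cf <- amount_at_time(p, rg, tt, mw = mw)
    a_ode <- amount_trajectory_ode(p, rg, tt, mw = mw)$amount_ng
    worst <- max(worst, max(abs(a_cf - a_ode) / pmax(a_cf, 1e-12)))
  }
  expect_lt(worst, 1e-6)
})

test_that("the model is linear: combination = injection + immersion", {
  p <- cy3a_params(1)
  tt <- c(0.25, 1, 3, 6, 24, 48)
  comb <- amount_at_time(p, exposure_regimen("combination", 10, 2), tt,
                         mw = 530.14)
  inj <- amount_at_time(p, exposure_regimen("PC", dose_mg_per_kg = 2), tt)
  imm <- amount_at_time(p, exposure_regimen("immersion", 10), tt, mw = 530.14)
  expect_equal(comb, inj + imm, tolerance = 1e-12)
  # injection-only strictly decreasing, immersion-only strictly increasing
  expect_true(all(diff(inj) < 0))
  expect_true(all(diff(imm) > 0))
})

test_that("closed-form AUC agrees with a fine trapezoid and its limits", {
  p <- cy3a_params(1)
  inj <- exposure_regimen("PC", dose_mg_per_kg = 2)
  comb <- exposure_regimen("combination", 10, 2)

  expect_equal(pk_auc(p, inj, 5, 5), 0)
  # injection-only 0-inf limit is Dose/ke
  expect_equal(pk_auc(p, inj, 0, 1e6), 0.5 / 0.049, tolerance = 1e-9)
  # CY3A injection 0-48 h: 0.5 * (1 - e^-2.352)/0.049
  expect_equal(pk_auc(p, inj, 0, 48), 0.5 * (1 - exp(-0.049 * 48)) / 0.049)
  expect_equal(pk_auc(p, inj, 0, 48), 9.23, tolerance = 1e-3)

  grid <- seq(0, 48, length.out = 1e4)
  a <- amount_at_time(p, comb, grid, mw = 530.14)
  trap <- sum(diff(grid) * (head(a, -1) + tail(a, -1)) / 2)
  expect_equal(pk_auc(p, comb, 0, 48, mw = 530.14), trap, tolerance = 1e-4)
  expect_error(pk_auc(p, inj, 10, 2), class = "zfpk_invalid_interval")
})

test_that("regimen invariants are enforced", {
  expect_error(exposure_regimen("immersion", medium_conc_um = 0),
               class = "zfpk_invalid_input")
  expect_error(exposure_regimen("combination", medium_conc_um = 10),
               class = "zfpk_invalid_input")
  expect_error(exposure_regimen("PC", dose_mg_per_kg = 2,
                                sampling_times_h = c(3, 1)),
               class = "zfpk_invalid_input")
  expect_error(pk_parameters(fluor = 0, ke = 0.1, q = 0),
               class = "zfpk_invalid_input")
})
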