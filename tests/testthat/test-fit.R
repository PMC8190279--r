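test_that("half-life identity and guards", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.052), 13.33, tolerance = 1e-3)
  expect_equal(half_life(0.011), 63.01, tolerance = 1e-3)
  expect_error(half_life(0), class = "zfpk_invalid_parameter")
})

test_that("initial estimates land near truth on noiseless data", {
  sim <- simulate_cy3a(seed = 1, cv = 0)
  est <- initial_estimates(sim, "CY3A")
  expect_lt(abs(est$ke - 0.049) / 0.049, 0.10)
  expect_lt(abs(est$fluor - 5000) / 5000, 0.10)
  expect_gt(est$q, 0)

  # all-zero immersion signal: q clipped to a positive floor and flagged
  zero <- sim
  imm_idx <- zero$observations$route == "immersion"
  zero$observations$rfu[imm_idx] <- 0
  est0 <- initial_estimates(zero, "CY3A")
  expect_true(attr(est0, "clipped"))
  expect_gt(est0$q, 0)
})

test_that("noiseless data are recovered to high relative accuracy from perturbed starts", {
  sim <- simulate_cy3a(seed = 2, cv = 0, n_replicates = 3)
  truth <- cy3a_params(5000)
  for (fac in c(0.5, 1.5)) {
    start <- pk_parameters(truth$fluor * fac, truth$ke * fac, truth$q * fac)
    fit <- fit_pk(sim, "CY3A", start = start)
    expect_lt(abs(fit$params$fluor - truth$fluor) / truth$fluor, 1e-4)
    expect_lt(abs(fit$params$ke - truth$ke) / truth$ke, 1e-4)
    expect_lt(abs(fit$params$q - truth$q) / truth$q, 1e-4)
    expect_true(fit$converged)
  }
  fit <- fit_pk(sim, "CY3A")
  expect_lt(fit$residual_standard_error, 1e-6)
  expect_equal(fit$half_life_h, log(2) / fit$params$ke)
  expect_equal(fit$n_used + fit$n_censored, 54)
})

test_that("parameter recovery is accurate at CV 10 percent", {
  errs <- sapply(1:15, function(s) {
    sim <- simulate_cy3a(seed = s, cv = 0.1)
    fit <- fit_pk(sim, "CY3A")
    c(ke = abs(fit$params$ke - 0.049) / 0.049,
      q = abs(fit$params$q - 8.37e-9) / 8.37e-9)
  })
  expect_lt(median(errs["ke", ]), 0.05)
  expect_lt(median(errs["q", ]), 0.05)
})

test_that("rescaling all rfu rescales fluor and leaves ke, q unchanged", {
  sim <- simulate_cy3a(seed = 4, cv = 0.1)
  f1 <- fit_pk(sim, "CY3A")
  sim$observations$rfu <- sim$observations$rfu * 37
  f2 <- fit_pk(sim, "CY3A")
  expect_equal(f2$params$fluor / f1$params$fluor, 37, tolerance = 1e-6)
  expect_equal(f2$params$ke, f1$params$ke, tolerance = 1e-8)
  expect_equal(f2$params$q, f1$params$q, tolerance = 1e-8)
})

test_that("residual censoring flags quench artifacts and is monotone", {
  q <- quench_spec(cutoff_time_h = 1, attenuation = 0.5)
  sim <- simulate_cy3a(seed = 6, cv = 0.1, quench = q)
  res <- fit_pk_censored(sim, "CY3A")
  obs <- res$dataset$observations
  affected <- obs$time_h < 1 & obs$route %in% c("PC", "IP")
  expect_gte(mean(obs$censored[affected]), 0.9)
  expect_lte(res$rounds, fit_options()$max_censor_rounds)
  # censored set only grows under a further round
  more <- censor_outliers(res$dataset, res$fit)
  expect_true(all(more$observations$censored[obs$censored]))

  # noiseless data: nothing censored
  clean <- fit_pk_censored(simulate_cy3a(seed = 6, cv = 0), "CY3A")
  expect_identical(sum(clean$dataset$observations$censored), 0L)

  # infinite threshold is a no-op
  fit <- fit_pk(sim, "CY3A")
  same <- censor_outliers(sim, fit, fit_options(censor_threshold = Inf))
  expect_identical(same$observations, sim$observations)
})

test_that("window censoring drops early injection points only", {
  sim <- simulate_cy3a(seed = 8, cv = 0.1,
                       quench = quench_spec(attenuation = 0.3))
  fit <- fit_pk(sim, "CY3A")
  opts <- fit_options(censor_mode = "window", window_cutoff_h = 1)
  out <- censor_outliers(sim, fit, opts)
  obs <- out$observations
  expect_true(all(obs$censored[obs$route %in% c("PC", "IP") & obs$time_h < 1]))
  expect_false(any(obs$censored[obs$route == "immersion"]))
  expect_false(any(obs$censored[obs$time_h >= 1]))
})

test_that("excess censoring is refused", {
  sim <- simulate_cy3a(seed = 9, cv = 0.05, n_replicates = 4)
  fit <- fit_pk(sim, "CY3A")
  # a tiny threshold would censor nearly everything
  expect_error(censor_outliers(sim, fit, fit_options(censor_threshold = 1e-6)),
               class = "zfpk_excess_censoring")
})

test_that("residual diagnostics are unbiased bookkeeping", {
  sim <- simulate_cy3a(seed = 10, cv = 0)
  fit <- fit_pk(sim, "CY3A")
  diag <- residual_diagnostics(sim, fit)
  expect_identical(nrow(diag), fit$n_used)
  expect_true(all(abs(diag$residual) < 1e-6))

  # standardized residual bias near zero across seeds on well-specified fits
  bias <- sapply(1:10, function(s) {
    sim <- simulate_cy3a(seed = s, cv = 0.1)
    fit <- fit_pk(sim, "CY3A")
    mean(residual_diagnostics(sim, fit)$std_residual)
  })
  expect_true(all(abs(bias) < 0.2))
})

test_that("single-route data trigger an identifiability warning", {
  sim <- simulate_cy3a(seed = 12, cv = 0.05, routes = "PC")
  expect_warning(fit_pk(sim, "CY3A"), class = "zfpk_identifiability_warning")
})
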