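test_that("centered-quadratic OLS matches the normal-equations oracle", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(7); y <- rnorm(7)
    m <- fit_centered_quadratic(x, y)
    oracle <- normal_equations_quadratic(x, y)
    expect_equal(unname(m$coefficients), oracle$beta, tolerance = 1e-10)
    expect_equal(m$fitted, oracle$fitted, tolerance = 1e-10)
    expect_equal(m$r2_adj, oracle$r2_adj, tolerance = 1e-10)
    expect_equal(m$rmse, oracle$rmse, tolerance = 1e-10)
  }
})

test_that("fit statistics satisfy their defining identities", {
  cmp <- reference_compounds()
  m <- fit_centered_quadratic(cmp$logd, reference_pk_parameters()$q, "Q")
  n <- m$n; p <- 2
  expect_equal(m$r2_adj, 1 - (1 - m$r2) * (n - 1) / (n - p - 1))
  sse <- sum((reference_pk_parameters()$q - m$fitted)^2)
  expect_equal(m$rmse, sqrt(sse / (n - p - 1)))
  st <- regression_stats(m)
  expect_equal(st$r2_adj, m$r2_adj)
  # perfect quadratic: exact fit
  y <- 2 - 0.5 * cmp$logd + 3 * (cmp$logd + 1)^2
  perfect <- fit_centered_quadratic(cmp$logd, y)
  expect_equal(perfect$r2_adj, 1, tolerance = 1e-10)
  expect_lt(perfect$rmse, 1e-10)
  expect_lt(perfect$p_value, 1e-10)
  expect_error(fit_centered_quadratic(rep(1, 5), rnorm(5)),
               class = "zfpk_rank_deficient")
  expect_error(fit_centered_quadratic(rnorm(5), rep(2, 5)),
               class = "zfpk_undefined_r2")
})

test_that("predictions are invariant to the centering constant", {
  cmp <- reference_compounds()
  y <- reference_pk_parameters()$q
  m <- fit_centered_quadratic(cmp$logd, y)
  for (c0 in c(0, -0.179, 1)) {
    X <- cbind(1, cmp$logd, (cmp$logd - c0)^2)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(as.vector(X %*% beta), m$fitted, tolerance = 1e-9)
  }
})

test_that("reference-panel regressions reproduce the known fit statistics", {
  cmp <- reference_compounds()
  pk <- reference_pk_parameters()
  mq <- fit_centered_quadratic(cmp$logd, pk$q, "Q")
  expect_equal(unname(mq$coefficients["linear"]), 1.696e-9, tolerance = 0.01)
  expect_equal(mq$r2_adj, 0.817, tolerance = 0.01)
  expect_equal(mq$rmse, 1.20e-9, tolerance = 0.01)
  expect_equal(mq$center, -0.177, tolerance = 0.02)

  m3 <- fit_centered_quadratic(cmp$logd, reference_re(3), "RE_3h")
  expect_equal(m3$r2_adj, 0.774, tolerance = 0.02)
  m48 <- fit_centered_quadratic(cmp$logd, reference_re(48), "RE_48h")
  expect_equal(m48$r2_adj, 0.755, tolerance = 0.02)
  expect_equal(m48$rmse, 0.483, tolerance = 0.02)
  expect_equal(unname(m48$coefficients["linear"]), 0.539, tolerance = 0.02)
})

test_that("covariance screening retains only mutually low-correlated descriptors", {
  cmp <- reference_compounds()
  desc <- cmp[, c("logd", "mw", "rotor", "hba", "hbd", "mr", "tpsa")]
  scr <- covariance_screen(desc, threshold = 0.7)
  # the screen's matrix matches brute-force pairwise correlations
  brute <- outer(names(desc), names(desc),
                 Vectorize(function(a, b) cor(desc[[a]], desc[[b]])))
  dimnames(brute) <- list(names(desc), names(desc))
  expect_equal(scr$correlation, brute, tolerance = 1e-12)
  kept <- scr$correlation[scr$kept, scr$kept]
  expect_true(all(abs(kept[upper.tri(kept)]) <= 0.7))

  # duplicate columns: the copy is dropped
  dup <- data.frame(a = cmp$logd, b = cmp$logd)
  expect_identical(covariance_screen(dup)$kept, "a")
  # threshold 1 keeps everything non-constant
  expect_identical(covariance_screen(desc, threshold = 1)$kept, names(desc))
  # constant column flagged and excluded
  expect_warning(out <- covariance_screen(cbind(desc, konst = 1)),
                 class = "zfpk_constant_column")
  expect_false("konst" %in% out$kept)
})

test_that("stepwise selection finds real signal and rejects noise", {
  cmp <- reference_compounds()
  desc <- cmp[covariance_screen(cmp[, c("logd", "mw", "rotor", "hba",
                                        "hbd", "mr", "tpsa")])$kept]
  # exact quadratic in LogD: both LogD terms selected and significant
  y <- 1 + 2 * cmp$logd + 3 * (cmp$logd - mean(cmp$logd))^2
  hit <- stepwise_select(desc, y)
  expect_true(hit$significant)
  expect_setequal(hit$terms, c("logd", "logd_csq"))

  # pure-noise responses: mostly no significant model (the null behaviour
  # expected for responses like ke and t1/2)
  nosig <- 0
  for (s in 1:40) {
    set.seed(s)
    r <- stepwise_select(desc, rnorm(7))
    if (!r$significant) nosig <- nosig + 1
  }
  expect_gte(nosig / 40, 0.7)
})

test_that("the full QSPkR analysis reports the lipophilicity models", {
  cmp <- reference_compounds()
  desc <- cmp[, c("logd", "mw", "rotor", "hba", "hbd", "mr", "tpsa")]
  pk <- reference_pk_parameters()
  responses <- data.frame(q = pk$q, ke = pk$ke, t_half = pk$t_half,
                          re_3h = reference_re(3), re_48h = reference_re(48))
  out <- qspkr_analysis(desc, responses)
  expect_true(all(c("q", "re_3h", "re_48h") %in% out$report$response))
  # rate constants yield no significant structure-PK model
  expect_false("ke" %in% out$report$response)
  expect_false("t_half" %in% out$report$response)
  qrow <- out$report[out$report$response == "q", ]
  expect_equal(qrow$r2_adj, 0.817, tolerance = 0.01)
})
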