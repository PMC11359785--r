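truth <- mem_params()

test_that("IV bolus prediction starts at dose/Vc", {
  d <- study_design("iv", 0.25, sampling_times_h = c(1e-9, 1, 24))
  mu <- predict_means(truth, d)
  vc <- truth$vc_fraction * truth$vss_per_kg * truth$body_weight
  expect_equal(mu[1], 0.25 * 1e6 / vc * 1000 / 1000, tolerance = 1e-6)
  # (mg -> ug, ug/L -> pg/mL)
})

test_that("oral prediction tends to the F-scaled IV profile as ka grows", {
  fast <- truth
  fast$ka <- 1e5
  t <- c(2, 6, 12, 24, 48)
  oral <- predict_means(fast, study_design("oral", 0.25, t))
  iv <- predict_means(truth, study_design("iv", 0.25, t))
  expect_equal(oral, truth$f_oral * iv, tolerance = 1e-3)
})

test_that("repeated dosing superposes shifted single-dose solutions", {
  t <- c(1, 4, 8, 12, 13, 16, 24, 48)
  two <- predict_means(truth, study_design("oral", 0.75, t,
                                           dose_times_h = c(0, 12)))
  one_a <- predict_means(truth, study_design("oral", 0.75, t))
  one_b <- predict_means(truth, study_design("oral", 0.75, t,
                                             dose_times_h = 12))
  expect_equal(two, one_a + one_b, tolerance = 1e-12)
})

test_that("the efavirenz arm uses the induced clearance", {
  t <- c(24, 48, 72)
  base <- predict_means(truth, study_design("iv", 0.25, t))
  efv <- predict_means(truth, study_design("iv", 0.25, t, efv = TRUE))
  expect_true(all(efv < base))
})

test_that("implant predictions match the PBPK quasi-steady state when aligned", {
  # parameterize the reference model with the calibrated PBPK clearance
  p <- truth
  p$cl <- attr(simulate_profile(cal_default$subject, cal_default$pk,
                                dose_event("implant", 150), 12), "cl_plasma")
  late_h <- c(6, 12, 24, 36, 48, 60) * 365.25 * 24 / 12
  mu <- predict_means(p, study_design("implant", 150, late_h))
  sch <- release_schedule()
  qss <- steady_state_conc(release_rate(sch, late_h / (365.25 * 24 / 12)), p$cl)
  expect_equal(mu, qss, tolerance = 0.02)
})

test_that("unsupported routes are refused", {
  expect_error(study_design("sublingual", 1, 1:3))
})

test_that("adaptive quadrature matches brute-force integration", {
  ds <- gen_trial_means(truth, seed = 7)
  la <- marginal_loglik(truth, ds, method = "agq", nodes = 9)
  lt <- marginal_loglik(truth, ds, method = "trapezoid")
  expect_lt(abs(la - lt), 1e-4)
  # more nodes should not change the answer materially
  la21 <- marginal_loglik(truth, ds, method = "agq", nodes = 21)
  expect_lt(abs(la - la21), 1e-4)
})

test_that("Gauss-Hermite rule integrates low-order polynomials exactly", {
  gh <- gauss_hermite(9)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^4), 3 * sqrt(pi) / 4, tolerance = 1e-12)
})

test_that("noise-free data are recovered exactly and fit never worsens the start", {
  quiet <- truth
  quiet$omega_f <- 0
  quiet$sigma_prop <- 0.001
  ds <- gen_trial_means(quiet, seed = TEST_SEED)
  f <- fit_mem(ds, init = quiet,
               estimate = c("cl", "cl_efv", "f_oral", "ka"),
               n_restarts = 2, seed = TEST_SEED)
  expect_gte(f$loglik, f$init_loglik)
  expect_equal(f$params$cl, quiet$cl, tolerance = 0.005)
  expect_equal(f$params$cl_efv, quiet$cl_efv, tolerance = 0.005)
  expect_equal(f$params$f_oral, quiet$f_oral, tolerance = 0.005)
  est <- f$estimates
  expect_true(all(c("estimate", "se", "lower95", "upper95") %in% names(est)))
})

test_that("oral-only data are rejected as non-identifiable in F", {
  ds <- gen_trial_means(truth, designs = list(
    study_design("oral", 0.25, c(1, 2, 4, 8, 24), study_id = "a"),
    study_design("oral", 0.75, c(1, 2, 4, 8, 24), study_id = "b")
  ), seed = TEST_SEED)
  expect_error(fit_mem(ds, init = truth), "identifiable")
})

test_that("datasets round-trip through the CSV dialect", {
  ds <- gen_trial_means(truth, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mem_csv(ds, path)
  back <- read_mem_csv(path)
  expect_equal(length(back), length(ds))
  for (i in seq_along(ds)) {
    j <- which(vapply(back, function(b) {
      identical(b$design$study_id, ds[[i]]$design$study_id) &&
        identical(b$design$route, ds[[i]]$design$route) &&
        identical(b$design$efv, ds[[i]]$design$efv)
    }, logical(1)))[1]
    expect_equal(back[[j]]$conc, ds[[i]]$conc, tolerance = 1e-8)
    expect_equal(back[[j]]$design$dose_times_h, ds[[i]]$design$dose_times_h)
  }
})
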