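months_grid <- c(0, 1, 3, 6, 12, 24, 36, 48, 60)

test_that("ODE and closed-form solutions agree on every route", {
  cal <- cal_default
  # implant
  d <- dose_event("implant", 150)
  pa <- simulate_profile(cal$subject, cal$pk, d, months_grid, method = "analytic")
  po <- simulate_profile(cal$subject, cal$pk, d, months_grid, method = "ode")
  expect_equal(po$total_pg_per_ml, pa$total_pg_per_ml, tolerance = 1e-6)
  # oral
  th <- seq(0, 72, by = 2)
  od <- dose_event("oral", 0.25)
  expect_equal(
    simulate_profile(cal$subject, cal$pk, od, th, method = "ode")$total_pg_per_ml,
    simulate_profile(cal$subject, cal$pk, od, th, method = "analytic")$total_pg_per_ml,
    tolerance = 1e-6)
  # IV bolus
  iv <- dose_event("iv_infusion", 0.25)
  th2 <- seq(0.5, 72, by = 1.5)
  expect_equal(
    simulate_profile(cal$subject, cal$pk, iv, th2, method = "ode")$total_pg_per_ml,
    simulate_profile(cal$subject, cal$pk, iv, th2, method = "analytic")$total_pg_per_ml,
    tolerance = 1e-6)
  # infusion over 1 h
  ivf <- dose_event("iv_infusion", 0.25, duration = 1)
  expect_equal(
    simulate_profile(cal$subject, cal$pk, ivf, th2, method = "ode")$total_pg_per_ml,
    simulate_profile(cal$subject, cal$pk, ivf, th2, method = "analytic")$total_pg_per_ml,
    tolerance = 1e-6)
})

test_that("implant solution matches rate/CL in the slowly-varying regime", {
  cal <- cal_default
  d <- dose_event("implant", 150)
  late <- c(6, 12, 24, 36, 48, 60)
  prof <- simulate_profile(cal$subject, cal$pk, d, late, method = "ode")
  qss <- steady_state_conc(release_rate(d$schedule, late),
                           attr(prof, "cl_plasma"))
  expect_equal(prof$total_pg_per_ml, qss, tolerance = 0.02)
})

test_that("the linear system is exactly dose-proportional", {
  cal <- cal_default
  p1 <- simulate_profile(cal$subject, cal$pk, dose_event("implant", 150),
                         months_grid, method = "analytic")
  p2 <- simulate_profile(cal$subject, cal$pk, dose_event("implant", 300),
                         months_grid, method = "analytic")
  expect_equal(p2$total_pg_per_ml, 2 * p1$total_pg_per_ml, tolerance = 1e-12)
  p1o <- simulate_profile(cal$subject, cal$pk, dose_event("implant", 150),
                          months_grid, method = "ode")
  p2o <- simulate_profile(cal$subject, cal$pk, dose_event("implant", 300),
                          months_grid, method = "ode")
  expect_equal(p2o$total_pg_per_ml[-1] / p1o$total_pg_per_ml[-1],
               rep(2, length(months_grid) - 1), tolerance = 1e-3)
})

test_that("unbound concentration is exactly fu times total", {
  cal <- cal_default
  for (m in c("analytic", "ode")) {
    prof <- simulate_profile(cal$subject, cal$pk, dose_event("implant", 150),
                             months_grid, method = m)
    expect_identical(prof$unbound_pg_per_ml, cal$pk$fu * prof$total_pg_per_ml)
    expect_true(all(prof$total_pg_per_ml >= 0))
  }
})

test_that("the ODE path conserves mass to integrator tolerance", {
  cal <- cal_default
  for (d in list(dose_event("implant", 150),
                 dose_event("oral", 0.75, n_doses = 2, interval = 12),
                 dose_event("iv_infusion", 0.25, duration = 0.5))) {
    tg <- if (d$route == "implant") months_grid else seq(0, 96, by = 4)
    prof <- simulate_profile(cal$subject, cal$pk, d, tg, method = "ode")
    expect_lt(attr(prof, "mass_balance"), 1e-8)
  }
})

test_that("oral dose over AUC reproduces apparent oral clearance", {
  cal <- cal_default
  th <- seq(0, 1000, by = 0.1)
  prof <- simulate_profile(cal$subject, cal$pk, dose_event("oral", 0.25), th,
                           method = "analytic")
  auc_pg_ml_h <- trapz(th, prof$total_pg_per_ml)
  cl_f <- 0.25 * 1e9 / (auc_pg_ml_h * 1000)  # mg -> pg; mL -> L
  expect_equal(cl_f, oral_bioavailability(cal$pk, cal$subject)$cl_over_f,
               tolerance = 1e-3)
})

test_that("oral bioavailability composes its factors as Fa*Fg*Fh", {
  cal <- cal_default
  ob <- oral_bioavailability(cal$pk, cal$subject)
  # Fh = 1 - CL_b/Q with CL_b = 5.86/0.671 = 8.733 and Q = 87 gives F = 0.840
  expect_equal(ob$fh, 0.899618, tolerance = 1e-5)
  expect_equal(ob$f, 0.84, tolerance = 1e-10)
  expect_equal(ob$f, ob$fa * ob$fg * ob$fh)
  # no gut or hepatic loss -> F = Fa
  pk2 <- cal$pk
  pk2$fg_baseline <- 1
  pk2$clint_u_total <- 1e-9
  expect_equal(oral_bioavailability(pk2, cal$subject)$f, pk2$fa,
               tolerance = 1e-9)
})

test_that("uncalibrated parameter sets are refused", {
  expect_error(simulate_profile(physiology(), victim_pk(),
                                dose_event("implant", 150), months_grid),
               "retrograde_clint")
  expect_error(oral_bioavailability(victim_pk(), physiology()), "calibrated")
  pk <- retrograde_clint(reference_set(), physiology(), victim_pk())
  expect_error(simulate_profile(physiology(), pk, dose_event("oral", 0.25),
                                0:24), "fg_baseline")
})

test_that("profiles serialize to the tidy CSV layout", {
  cal <- cal_default
  prof <- simulate_profile(cal$subject, cal$pk, dose_event("implant", 150),
                           months_grid)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path, scenario_id = 1, subject_id = "typical")
  df <- read.csv(path)
  expect_named(df, c("scenario_id", "subject_id", "time_months",
                     "total_pg_per_ml", "unbound_pg_per_ml", "cl_L_per_h"))
  expect_equal(df$total_pg_per_ml, prof$total_pg_per_ml)
})
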