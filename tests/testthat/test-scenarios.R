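sc_default <- run_scenarios(cal_default)

test_that("scenario ratios reproduce the induction calibration and dose linearity", {
  at12 <- sc_default[sc_default$month == 12, ]
  r <- function(id) at12$ratio_to_control[at12$scenario_id == id]
  expect_equal(r(2), 0.68, tolerance = 1e-6)
  expect_equal(r(3), 0.72, tolerance = 1e-6)
  expect_equal(r(4), 2 * r(2), tolerance = 1e-12)  # doubled implant
  expect_equal(r(5), 2 * r(3), tolerance = 1e-12)
})

test_that("ratio to control is time-invariant at quasi-steady state", {
  for (id in 2:5) {
    rows <- sc_default[sc_default$scenario_id == id & sc_default$month >= 6, ]
    expect_lt(diff(range(rows$ratio_to_control)) / mean(rows$ratio_to_control),
              0.01)
  }
  # and also under the exact transient solution
  sc_an <- run_scenarios(cal_default, method = "analytic")
  rows <- sc_an[sc_an$scenario_id == 2 & sc_an$month >= 6, ]
  expect_lt(diff(range(rows$ratio_to_control)) / mean(rows$ratio_to_control),
            0.01)
})

test_that("control scenario tracks the published concentration decline", {
  ctrl <- sc_default[sc_default$scenario_id == 1, ]
  expect_equal(ctrl$total_pg_per_ml[ctrl$month == 0], 0)
  expect_equal(ctrl$total_pg_per_ml[ctrl$month == 12], 284.414, tolerance = 1e-4)
  expect_equal(ctrl$total_pg_per_ml[ctrl$month == 36], 213.311, tolerance = 1e-4)
  expect_equal(ctrl$total_pg_per_ml[ctrl$month == 60], 177.759, tolerance = 1e-4)
})

test_that("turnover-mode induction converges to the static result on month scales", {
  sc_turn <- run_scenarios(cal_default, induction_mode = "turnover")
  late <- sc_default$month >= 1
  expect_equal(sc_turn$total_pg_per_ml[late], sc_default$total_pg_per_ml[late],
               tolerance = 0.01)
})

test_that("ratios require a control scenario", {
  no_ctrl <- default_scenarios()[2:3, ]
  expect_error(run_scenarios(cal_default, scenarios = no_ctrl), "control")
})

test_that("population summaries bracket the typical subject", {
  pop <- gen_population(population_spec(n_subjects = 200, seed = TEST_SEED),
                        cal_default$pk, cal_default$subject)
  sc <- run_scenarios(cal_default, population = pop)
  rows <- sc[sc$month >= 1, ]
  expect_true(all(rows$pop_p05_total <= rows$pop_median_total))
  expect_true(all(rows$pop_median_total <= rows$pop_p95_total))
  # under the default CVs the 200-subject median stays within 3% of typical
  expect_equal(rows$pop_median_total / rows$total_pg_per_ml,
               rep(1, nrow(rows)), tolerance = 0.03)
  expect_equal(rows$pop_median_unbound, cal_default$pk$fu * rows$pop_median_total)
})

test_that("fraction-unbound sweep is monotone with fixed unbound intrinsic clearance", {
  fs <- run_fu_sweep(cal_default)
  expect_equal(nrow(fs), 12)
  expect_true(all(diff(fs$cl_L_per_h) > 0))
  expect_true(all(diff(fs$total_pg_per_ml) < 0))
  expect_true(all(diff(fs$unbound_pg_per_ml) > 0))
  expect_equal(fs$unbound_pg_per_ml, fs$fu * fs$total_pg_per_ml)
  expect_error(run_fu_sweep(cal_default, fu_grid = c(0.01, 1.2)), "within")
})

test_that("fu sweep reproduces the doubled-binding contrast", {
  fs <- run_fu_sweep(cal_default, lng_mg = 300, efv_mg = 600)
  t13 <- fs$total_pg_per_ml[fs$fu == 0.013]
  t26 <- fs$total_pg_per_ml[fs$fu == 0.026]
  expect_equal(t13, 386.80, tolerance = 1e-4)
  expect_equal(t26, 221.95, tolerance = 1e-4)
  # unbound rises ~15% while total nearly halves
  expect_equal(fs$unbound_pg_per_ml[fs$fu == 0.026] /
                 fs$unbound_pg_per_ml[fs$fu == 0.013], 1.1476,
               tolerance = 1e-3)
})

test_that("exposure sweep saturates: monotone ratios with diminishing decrements", {
  es <- run_exposure_sweep(cal_default)
  expect_equal(es$ratio_to_reference[es$efv_mg == 600], 1)
  expect_true(all(diff(es$ratio_to_reference) < 0))
  drop_12_24 <- es$total_pg_per_ml[es$efv_mg == 1200] -
    es$total_pg_per_ml[es$efv_mg == 2400]
  drop_24_48 <- es$total_pg_per_ml[es$efv_mg == 2400] -
    es$total_pg_per_ml[es$efv_mg == 4800]
  expect_lt(drop_24_48, drop_12_24)
  expect_equal(es$unbound_pg_per_ml, cal_default$pk$fu * es$total_pg_per_ml)
})
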