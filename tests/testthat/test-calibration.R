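test_that("retrograde calibration inverts the well-stirred model exactly", {
  cal <- cal_default
  # closed-form inversion: fu_b*CLint = 9.7077 L/h, i.e. CLint_u ~ 501 L/h
  expect_equal(cal$pk$clint_u_total, 501.0674, tolerance = 1e-6)
  achieved <- well_stirred_cl(cal$pk$fu, cal$pk$bp_ratio,
                              cal$pk$clint_u_total,
                              cal$subject$hepatic_blood_flow)$cl_plasma
  expect_equal(achieved, 5.86, tolerance = 1e-9)
  expect_equal(cal$pk$fm_cyp3a4, 0.16)
})

test_that("the sensitivity-scan mode agrees with the closed form", {
  pk_scan <- retrograde_clint(reference_set(), physiology(), victim_pk(),
                              mode = "grid_scan")
  expect_equal(pk_scan$clint_u_total, cal_default$pk$clint_u_total,
               tolerance = 1e-6)
})

test_that("infeasible and degenerate clearance targets are handled", {
  expect_error(retrograde_clint(reference_set(cl_baseline = 87 * 0.671 + 1),
                                physiology(), victim_pk()),
               "flow limit")
  tiny <- retrograde_clint(reference_set(cl_baseline = 1e-6),
                           physiology(), victim_pk())
  expect_lt(tiny$clint_u_total, 1e-3)
})

test_that("gut availability calibration reproduces oral F and CL/F", {
  cal <- cal_default
  expect_equal(cal$pk$fg_baseline, 0.933730, tolerance = 1e-5)
  ob <- oral_bioavailability(cal$pk, cal$subject)
  expect_equal(ob$f, 0.84, tolerance = 1e-10)
  expect_equal(ob$cl_over_f, 6.97619, tolerance = 1e-5)
  # a target F above Fa*Fh would need Fg > 1
  expect_error(calibrate_gut(reference_set(f_oral_baseline = 0.95),
                             cal$pk, cal$subject), "gut availability")
})

test_that("induction calibration solves the two-point Emax system", {
  ind <- cal_default$ind
  # required net hepatic folds via exact well-stirred inversion
  expect_equal(attr(ind, "fold600"), 4.450548, tolerance = 1e-6)
  expect_equal(attr(ind, "fold400"), 3.824321, tolerance = 1e-6)
  expect_gt(attr(ind, "fold600"), 3)
  # the Emax curve passes through both calibration points
  expect_equal(induction_fold(1, ind), attr(ind, "fold600"), tolerance = 1e-10)
  expect_equal(induction_fold(2 / 3, ind), attr(ind, "fold400"),
               tolerance = 1e-10)
})

test_that("the zero-extraction shortcut reproduces its known constants", {
  # in the linear (CL proportional to CLint) reading the folds are
  # (1/0.68 - 0.84)/0.16 = 3.9412 and (1/0.72 - 0.84)/0.16 = 3.4306,
  # and the 2x2 Emax solve gives Indmax ~5.07 at E600/IndC50 ~1.38
  ind <- calibrate_induction(reference_set(), induction_spec(),
                             method = "linear")
  expect_equal(attr(ind, "fold600"), 3.941176, tolerance = 1e-6)
  expect_equal(attr(ind, "fold400"), 3.430556, tolerance = 1e-6)
  expect_equal(ind$ind_max, 5.072464, tolerance = 1e-5)
  expect_equal(1 / ind$ind_c50, 1.38, tolerance = 1e-5)
})

test_that("single-pathway limit: fm near 1 needs only the ratio inverse", {
  ref <- reference_set(fm_cyp3a4 = 1 - 1e-9)
  ind <- calibrate_induction(ref, induction_spec(), method = "linear",
                             min_fold = NA)
  expect_equal(attr(ind, "fold600"), 1 / 0.68, tolerance = 1e-6)
})

test_that("calibrating to the induced-clearance pair is available as a switch", {
  cal <- cal_default
  ind <- calibrate_induction(cal$ref, induction_spec(), cal$pk, cal$subject,
                             target = "cl_pair")
  f600 <- attr(ind, "fold600")
  expect_gt(f600, 1)
  # forward check: the fold reproduces CL_efv
  pk_i <- apply_induction(cal$pk, f600)
  expect_equal(well_stirred_cl(pk_i$fu, pk_i$bp_ratio, pk_i$clint_u_total,
                               cal$subject$hepatic_blood_flow)$cl_plasma,
               cal$ref$cl_efv, tolerance = 1e-6)
})

test_that("full round trip reproduces every reference entry within 0.5%", {
  cal <- cal_default
  ws <- well_stirred_cl(cal$pk$fu, cal$pk$bp_ratio, cal$pk$clint_u_total,
                        cal$subject$hepatic_blood_flow)
  expect_equal(ws$cl_plasma / cal$ref$cl_baseline, 1, tolerance = 0.005)
  expect_equal(oral_bioavailability(cal$pk, cal$subject)$f /
                 cal$ref$f_oral_baseline, 1, tolerance = 0.005)
  sc <- run_scenarios(cal)
  r600 <- sc$ratio_to_control[sc$scenario_id == 2 & sc$month == 12]
  r400 <- sc$ratio_to_control[sc$scenario_id == 3 & sc$month == 12]
  expect_equal(r600 / cal$ref$conc_ratio_efv600, 1, tolerance = 0.005)
  expect_equal(r400 / cal$ref$conc_ratio_efv400, 1, tolerance = 0.005)
})

test_that("incompatible concentration ratios raise a named diagnostic", {
  # ratios too close: I400 barely above 1 while I600 is large -> no
  # saturating curve passes through both points at 2:3 exposure spacing
  ref_bad <- reference_set(conc_ratio_efv600 = 0.5, conc_ratio_efv400 = 0.99)
  expect_error(
    calibrate_induction(ref_bad, induction_spec(), cal_default$pk,
                        cal_default$subject),
    "Emax|E600")
})

test_that("the calibration report lists targets, achieved values and errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rep <- write_calibration_report(cal_default, path)
  expect_true(file.exists(path))
  expect_true(all(abs(rep$rel_error) < 0.005, na.rm = TRUE))
  df <- read.delim(path)
  expect_equal(nrow(df), 4)
})
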