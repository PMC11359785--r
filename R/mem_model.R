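#' Study design for the reference mixed-effects model
#'
#' One arm of one clinical trial contributing mean concentration-time data:
#' a single IV dose, one or more oral doses, or a subdermal implant, with
#' or without concomitant efavirenz.
#'
#' @param route `"iv"`, `"oral"` or `"implant"`.
#' @param dose_mg Dose per administration (oral/IV) or total implant load.
#' @param sampling_times_h Increasing, non-empty sampling times, h.
#' @param dose_times_h Administration times, h (oral/IV; default single
#'   dose at 0).
#' @param efv `TRUE` for an efavirenz co-administration arm.
#' @param study_id Identifier; arms sharing a `study_id` share the
#'   study-level random effect.
#' @return An object of class `study_design`.
#' @export
study_design <- function(route = c("iv", "oral", "implant"), dose_mg,
                         sampling_times_h, dose_times_h = 0,
                         efv = FALSE, study_id = NA_character_) {
  route <- match.arg(route)
  stopifnot(dose_mg > 0, length(sampling_times_h) >= 1,
            !is.unsorted(sampling_times_h, strictly = TRUE),
            all(sampling_times_h >= 0), all(dose_times_h >= 0))
  structure(list(route = route, dose_mg = dose_mg,
                 sampling_times_h = sampling_times_h,
                 dose_times_h = dose_times_h, efv = isTRUE(efv),
                 study_id = study_id),
            class = "study_design")
}

#' Parameters of the two-compartment mixed-effects reference model
#'
#' Fixed effects are the baseline and induced clearances, distribution
#' volume, intercompartmental clearance, absorption rate and oral
#' bioavailabilities; random structure is a study-level effect on F
#' (additive on the logit scale, keeping F in (0,1)) and proportional
#' residual error on mean concentrations. Defaults are the reported
#' point estimates where printed and declared values elsewhere.
#'
#' @param cl,cl_efv Plasma clearance without / with efavirenz, L/h.
#' @param vss_per_kg Steady-state volume, L/kg.
#' @param vc_fraction Central fraction of Vss.
#' @param q_inter Intercompartmental clearance, L/h.
#' @param ka First-order absorption rate, 1/h.
#' @param f_oral,f_oral_efv Oral bioavailability without / with efavirenz.
#' @param omega_f Between-study SD of F on the logit scale.
#' @param sigma_prop Proportional residual SD.
#' @param body_weight Typical body weight, kg (fixed, not estimated).
#' @return An object of class `mem_params`.
#' @export
mem_params <- function(cl = 5.86, cl_efv = 10.10, vss_per_kg = 2.27,
                       vc_fraction = 0.3, q_inter = 10.2, ka = 1.0,
                       f_oral = 0.84, f_oral_efv = 0.53,
                       omega_f = 0.3, sigma_prop = 0.1,
                       body_weight = 67.3) {
  stopifnot(cl > 0, cl_efv > 0, vss_per_kg > 0,
            vc_fraction > 0, vc_fraction < 1, q_inter > 0, ka > 0,
            f_oral > 0, f_oral <= 1, f_oral_efv > 0, f_oral_efv <= 1,
            omega_f >= 0, sigma_prop >= 0, body_weight > 0)
  structure(list(cl = cl, cl_efv = cl_efv, vss_per_kg = vss_per_kg,
                 vc_fraction = vc_fraction, q_inter = q_inter, ka = ka,
                 f_oral = f_oral, f_oral_efv = f_oral_efv,
                 omega_f = omega_f, sigma_prop = sigma_prop,
                 body_weight = body_weight),
            class = "mem_params")
}

#' Predicted mean concentrations for one study arm
#'
#' Closed-form two-compartment solutions per route: biexponential IV
#' bolus, first-order absorption for oral dosing (superposition over
#' repeated doses), and the exact response to the zero-order time-varying
#' implant input. The study-level random effect `eta_f` shifts logit(F)
#' for oral arms only (F does not enter IV or implant kinetics).
#'
#' @param params A [mem_params()].
#' @param design A [study_design()].
#' @param eta_f Study-level random effect on logit(F) (default 0: typical
#'   study).
#' @return Mean concentrations, pg/mL, at `design$sampling_times_h`.
#' @export
predict_means <- function(params, design, eta_f = 0) {
  stopifnot(inherits(params, "mem_params"), inherits(design, "study_design"))
  vss <- params$vss_per_kg * params$body_weight
  vc <- params$vc_fraction * vss
  vp <- vss - vc
  cl <- if (design$efv) params$cl_efv else params$cl
  macro <- twocpt_macro(cl, vc, vp, params$q_inter)
  t <- design$sampling_times_h
  dose_ug <- design$dose_mg * 1000

  conc_ug_l <- switch(
    design$route,
    iv = {
      out <- numeric(length(t))
      for (s in design$dose_times_h) {
        out <- out + twocpt_conc_iv_bolus(t - s, dose_ug, macro)
      }
      out
    },
    oral = {
      f0 <- if (design$efv) params$f_oral_efv else params$f_oral
      f <- stats::plogis(stats::qlogis(f0) + eta_f)
      out <- numeric(length(t))
      for (s in design$dose_times_h) {
        out <- out + twocpt_conc_oral(t - s, dose_ug, f, params$ka, macro)
      }
      out
    },
    implant = {
      sch <- release_schedule(scale = design$dose_mg / 150)
      segs <- release_segments(sch, max(t) + 1)
      twocpt_conc_zero_order(t, segs, macro)
    },
    stop("predict_means(): unsupported route '", design$route, "'")
  )
  conc_ug_l * 1000  # -> pg/mL
}
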