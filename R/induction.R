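#' Perpetrator exposure and CYP3A4 induction specification
#'
#' Reduced model of the perpetrator (efavirenz): daily dose maps linearly
#' to a steady-state driving exposure, which feeds an Emax-type induction
#' curve for CYP3A4 activity in liver and gut wall. The linear dose-to-
#' exposure map is justified by the flat within-day profiles of both drugs
#' (half-lives > 36 h); the `exposure_multiplier` is a dimensionless scale
#' standing in for metabolizer genotype (higher exposure in slow
#' metabolizers at the same dose). Exposure is expressed in units of the
#' reference exposure, i.e. the steady-state exposure of a 600 mg daily
#' dose in the typical woman, so `exposure_per_mg` defaults to 1/600.
#'
#' `ind_max` and `ind_c50` are calibrated against observed concentration
#' ratios by [calibrate_induction()] rather than copied from any external
#' perpetrator model; the constructor defaults are `NA` until then.
#'
#' @param ind_max Maximal fold-increase minus 1 of CYP3A4 activity.
#' @param ind_c50 Exposure at half-maximal induction (reference-exposure
#'   units).
#' @param exposure_per_mg Exposure per mg of daily dose (1/600 by
#'   definition of the reference unit).
#' @param exposure_multiplier Genotype stand-in multiplier (default 1).
#' @param kdeg_liver,kdeg_gut First-order CYP3A4 degradation rate constants,
#'   1/h, for the turnover (time-course) mode. Defaults 0.0193/h
#'   (enzyme turnover half-life about 36 h) in both tissues.
#' @return An object of class `induction_spec`.
#' @export
induction_spec <- function(ind_max = NA_real_, ind_c50 = NA_real_,
                           exposure_per_mg = 1 / 600,
                           exposure_multiplier = 1,
                           kdeg_liver = 0.0193, kdeg_gut = 0.0193) {
  if (!is.na(ind_max)) stopifnot(ind_max >= 0)
  if (!is.na(ind_c50)) stopifnot(ind_c50 > 0)
  stopifnot(exposure_per_mg > 0, exposure_multiplier > 0,
            kdeg_liver > 0, kdeg_gut > 0)
  structure(list(ind_max = ind_max, ind_c50 = ind_c50,
                 exposure_per_mg = exposure_per_mg,
                 exposure_multiplier = exposure_multiplier,
                 kdeg_liver = kdeg_liver, kdeg_gut = kdeg_gut),
            class = "induction_spec")
}

#' @export
print.induction_spec <- function(x, ...) {
  cat(sprintf("<induction_spec> Indmax %s, IndC50 %s (ref-exposure units)\n",
              format(x$ind_max, digits = 4), format(x$ind_c50, digits = 4)))
  cat(sprintf("  exposure/mg %.4g, multiplier %.3g, kdeg liver/gut %.3g/%.3g 1/h\n",
              x$exposure_per_mg, x$exposure_multiplier,
              x$kdeg_liver, x$kdeg_gut))
  invisible(x)
}

#' Steady-state perpetrator exposure from daily dose
#'
#' Linear in dose: `exposure = exposure_per_mg * dose_mg *
#' exposure_multiplier`. With the defaults, 600 mg daily maps to exposure
#' 1 (the reference unit) and 4800 mg to 8.
#'
#' @param dose_mg Daily perpetrator dose, mg (> 0). Vectorised.
#' @param spec An [induction_spec()].
#' @return Exposure in reference units.
#' @export
perpetrator_exposure <- function(dose_mg, spec) {
  stopifnot(inherits(spec, "induction_spec"))
  if (any(dose_mg <= 0)) {
    stop("perpetrator_exposure(): daily dose must be positive")
  }
  spec$exposure_per_mg * dose_mg * spec$exposure_multiplier
}

#' Fold-increase of CYP3A4 activity at a given perpetrator exposure
#'
#' Emax form `fold = 1 + ind_max * exposure / (ind_c50 + exposure)`:
#' strictly increasing and concave in exposure, saturating at
#' `1 + ind_max` — induction plateaus at high perpetrator exposure.
#'
#' @param exposure Exposure in reference units (>= 0). Vectorised.
#' @param spec A calibrated [induction_spec()].
#' @return Fold-increase >= 1.
#' @export
induction_fold <- function(exposure, spec) {
  stopifnot(inherits(spec, "induction_spec"), all(exposure >= 0))
  if (is.na(spec$ind_max) || is.na(spec$ind_c50)) {
    stop("induction_fold(): spec not calibrated; run calibrate_induction()")
  }
  1 + spec$ind_max * exposure / (spec$ind_c50 + exposure)
}

#' Apply CYP3A4 induction to the victim parameter set
#'
#' Only the CYP3A4 share of hepatic intrinsic clearance is induced:
#' `CLint_u' = CLint_u * ((1 - fm) + fm * fold_liver)`. Gut-wall
#' availability falls by the competing-rates inversion
#' `Fg' = Fg / (Fg + (1 - Fg) * fold_gut)` (the gut wall is assumed fully
#' CYP3A4-mediated). All other fields are unchanged.
#'
#' @param pk A calibrated [victim_pk()].
#' @param fold_liver,fold_gut Fold-increases >= 1 (gut defaults to liver).
#' @return The induced `victim_pk`.
#' @export
apply_induction <- function(pk, fold_liver, fold_gut = fold_liver) {
  stopifnot(inherits(pk, "victim_pk"), fold_liver >= 1, fold_gut >= 1)
  pk$clint_u_total <- pk$clint_u_total *
    ((1 - pk$fm_cyp3a4) + pk$fm_cyp3a4 * fold_liver)
  if (!is.na(pk$fg_baseline)) {
    fg <- pk$fg_baseline
    pk$fg_baseline <- fg / (fg + (1 - fg) * fold_gut)
  }
  pk
}

#' Time course of induction under enzyme turnover
#'
#' First-order approach of the induced activity to its steady-state fold:
#' `fold(t) = 1 + (fold_target - 1) * (1 - exp(-kdeg * t))`, assuming the
#' perpetrator starts at `t = 0` and its exposure is at steady state on the
#' enzyme-turnover time scale. With kdeg 0.0193/h, 96% of the full effect
#' is reached within one week, so month-scale implant results converge to
#' the static mode.
#'
#' @param fold_target Steady-state fold (>= 1).
#' @param kdeg Enzyme degradation rate constant, 1/h.
#' @param t_h Time since perpetrator start, h (>= 0). Vectorised.
#' @return Fold at `t_h`.
#' @export
enzyme_turnover <- function(fold_target, kdeg, t_h) {
  stopifnot(fold_target >= 1, kdeg > 0, all(t_h >= 0))
  1 + (fold_target - 1) * (1 - exp(-kdeg * t_h))
}
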