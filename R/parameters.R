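#' Levonorgestrel drug-specific parameter set
#'
#' Container for the victim-drug (levonorgestrel) parameters of the minimal
#' PBPK model. Binding and partitioning values are literature constants; the
#' whole-liver unbound intrinsic clearance `clint_u_total` and the baseline
#' gut-wall availability `fg_baseline` are placeholders until set by
#' [retrograde_clint()] and [calibrate_gut()], mirroring the retrograde way
#' such in-vitro-scale parameters are obtained when no direct assay exists.
#'
#' @param fu Fraction unbound in plasma (default 0.013, i.e. 98.7% bound to
#'   albumin and SHBG).
#' @param bp_ratio Blood-to-plasma concentration ratio (default 0.671).
#' @param fu_mic Fraction unbound in the microsomal incubation (default
#'   0.449); documentary, used only by [scale_clint_from_invitro()].
#' @param clint_u_total Whole-liver unbound intrinsic clearance, L/h.
#'   `NA` until calibrated.
#' @param fm_cyp3a4 Fraction of hepatic intrinsic clearance carried by
#'   CYP3A4 (default 0.16).
#' @param vss Steady-state volume of distribution, L/kg (default 2.27).
#' @param q_inter Intercompartmental clearance, L/h (default 10.2).
#' @param vc_fraction Fraction of Vss assigned to the central compartment
#'   (default 0.3; affects transients only, never steady state).
#' @param ka First-order oral absorption rate constant, 1/h (default 1).
#' @param fa Fraction absorbed from the gut lumen (default 1).
#' @param fg_baseline Baseline gut-wall availability; `NA` until calibrated.
#' @param clint_3a4_per_pmol Documentary in-vitro CYP3A4 intrinsic clearance,
#'   uL/min/pmol (default 0.0843). Not used by the calibrated model.
#' @param hlm_nonCyp3a4 Documentary non-CYP3A4 microsomal clearance,
#'   uL/min/mg protein (default 128). Not used by the calibrated model.
#' @return An object of class `victim_pk`.
#' @export
victim_pk <- function(fu = 0.013,
                      bp_ratio = 0.671,
                      fu_mic = 0.449,
                      clint_u_total = NA_real_,
                      fm_cyp3a4 = 0.16,
                      vss = 2.27,
                      q_inter = 10.2,
                      vc_fraction = 0.3,
                      ka = 1.0,
                      fa = 1.0,
                      fg_baseline = NA_real_,
                      clint_3a4_per_pmol = 0.0843,
                      hlm_nonCyp3a4 = 128) {
  stopifnot(fu > 0, fu <= 1, fu_mic > 0, fu_mic <= 1, bp_ratio > 0,
            fm_cyp3a4 >= 0, fm_cyp3a4 <= 1,
            vss > 0, q_inter > 0, vc_fraction > 0, vc_fraction < 1,
            ka > 0, fa > 0, fa <= 1)
  if (!is.na(clint_u_total)) stopifnot(clint_u_total >= 0)
  if (!is.na(fg_baseline)) stopifnot(fg_baseline > 0, fg_baseline <= 1)
  structure(list(
    fu = fu, bp_ratio = bp_ratio, fu_mic = fu_mic,
    clint_u_total = clint_u_total, fm_cyp3a4 = fm_cyp3a4,
    vss = vss, q_inter = q_inter, vc_fraction = vc_fraction,
    ka = ka, fa = fa, fg_baseline = fg_baseline,
    clint_3a4_per_pmol = clint_3a4_per_pmol,
    hlm_nonCyp3a4 = hlm_nonCyp3a4
  ), class = "victim_pk")
}

#' @export
print.victim_pk <- function(x, ...) {
  cat("<victim_pk> levonorgestrel parameter set\n")
  cat(sprintf("  fu %.4g  B/P %.4g  fm,CYP3A4 %.3g\n",
              x$fu, x$bp_ratio, x$fm_cyp3a4))
  cat(sprintf("  CLint,u total %s L/h  Fg %s\n",
              format(x$clint_u_total, digits = 5),
              format(x$fg_baseline, digits = 4)))
  cat(sprintf("  Vss %.3g L/kg (Vc fraction %.2g)  Q %.3g L/h  ka %.2g /h  Fa %.2g\n",
              x$vss, x$vc_fraction, x$q_inter, x$ka, x$fa))
  invisible(x)
}

#' System (physiology) parameters of the virtual subject
#'
#' The typical subject is a woman of reproductive age (18-45 years) with an
#' average weight of 67.3 kg. `liver_mass`, `mppgl` and `cyp3a4_abundance`
#' are documentary scaling constants used only by the optional in-vitro
#' scaling mode ([scale_clint_from_invitro()]); the calibrated model works
#' at whole-liver scale.
#'
#' @param body_weight Body weight, kg.
#' @param hepatic_blood_flow Hepatic blood flow, L/h of blood (default 87,
#'   about 1.45 L/min in an adult female).
#' @param liver_mass Liver mass, g (documentary).
#' @param mppgl Microsomal protein per gram of liver, mg/g (documentary).
#' @param cyp3a4_abundance Hepatic CYP3A4 abundance, pmol per mg microsomal
#'   protein (documentary).
#' @return An object of class `physiology`.
#' @export
physiology <- function(body_weight = 67.3,
                       hepatic_blood_flow = 87,
                       liver_mass = 1600,
                       mppgl = 40,
                       cyp3a4_abundance = 137) {
  stopifnot(body_weight > 0, hepatic_blood_flow > 0, liver_mass > 0,
            mppgl > 0, cyp3a4_abundance > 0)
  structure(list(
    body_weight = body_weight,
    hepatic_blood_flow = hepatic_blood_flow,
    liver_mass = liver_mass,
    mppgl = mppgl,
    cyp3a4_abundance = cyp3a4_abundance
  ), class = "physiology")
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> BW %.3g kg, hepatic blood flow %.3g L/h\n",
              x$body_weight, x$hepatic_blood_flow))
  invisible(x)
}

#' Scale whole-liver intrinsic clearance from in-vitro rates
#'
#' Exploration helper: scales a per-pmol CYP3A4 rate and a per-mg-protein
#' non-CYP3A4 microsomal rate to whole-liver unbound intrinsic clearance via
#' enzyme abundance, microsomal protein per gram of liver and liver mass,
#' dividing by the microsomal fraction unbound. The calibrated model does
#' not use this route (the retrograde calibration works directly at
#' whole-liver scale); it is provided to compare the documentary in-vitro
#' values against the calibrated whole-liver number.
#'
#' @param pk A [victim_pk()] carrying the documentary in-vitro values.
#' @param subject A [physiology()] carrying the scaling constants.
#' @return List with components `clint_u_cyp3a4`, `clint_u_other`,
#'   `clint_u_total` (all L/h, unbound) and the implied `fm_cyp3a4`.
#' @export
scale_clint_from_invitro <- function(pk, subject) {
  stopifnot(inherits(pk, "victim_pk"), inherits(subject, "physiology"))
  # uL/min -> L/h: * 60 / 1e6
  ul_min_to_l_h <- 60 / 1e6
  cyp <- pk$clint_3a4_per_pmol * subject$cyp3a4_abundance *
    subject$mppgl * subject$liver_mass * ul_min_to_l_h / pk$fu_mic
  oth <- pk$hlm_nonCyp3a4 * subject$mppgl * subject$liver_mass *
    ul_min_to_l_h / pk$fu_mic
  list(clint_u_cyp3a4 = cyp, clint_u_other = oth,
       clint_u_total = cyp + oth, fm_cyp3a4 = cyp / (cyp + oth))
}
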