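#' Well-stirred hepatic clearance
#'
#' The well-stirred (venous equilibration) liver model. Unbound fraction in
#' blood is `fu_b = fu / bp_ratio`; hepatic blood clearance is
#' `CL_b = Q * fu_b * CLint_u / (Q + fu_b * CLint_u)`, bounded above by the
#' hepatic blood flow `Q`; plasma clearance is `CL_b * bp_ratio`.
#'
#' @param fu Fraction unbound in plasma.
#' @param bp_ratio Blood-to-plasma concentration ratio.
#' @param clint_u Unbound whole-liver intrinsic clearance, L/h (may be 0).
#' @param q_hep_blood Hepatic blood flow, L/h.
#' @return List with `cl_plasma` (L/h), `cl_blood` (L/h) and `extraction`
#'   (hepatic extraction ratio `E = CL_b / Q`).
#' @examples
#' well_stirred_cl(0.013, 0.671, 501.07, 87)$cl_plasma  # ~5.86
#' @export
well_stirred_cl <- function(fu, bp_ratio, clint_u, q_hep_blood) {
  stopifnot(fu > 0, bp_ratio > 0, clint_u >= 0, q_hep_blood > 0)
  fu_b <- fu / bp_ratio
  x <- fu_b * clint_u
  cl_blood <- q_hep_blood * x / (q_hep_blood + x)
  list(cl_plasma = cl_blood * bp_ratio,
       cl_blood = cl_blood,
       extraction = cl_blood / q_hep_blood)
}

#' Invert the well-stirred model for intrinsic clearance
#'
#' Closed-form inverse of [well_stirred_cl()]: the unbound intrinsic
#' clearance that yields a given plasma clearance. Feasible only below the
#' flow limit `CL_plasma < Q * bp_ratio`.
#'
#' @inheritParams well_stirred_cl
#' @param cl_plasma Target plasma clearance, L/h.
#' @return Unbound whole-liver intrinsic clearance, L/h.
#' @export
invert_well_stirred <- function(cl_plasma, fu, bp_ratio, q_hep_blood) {
  stopifnot(fu > 0, bp_ratio > 0, q_hep_blood > 0, cl_plasma >= 0)
  cl_blood <- cl_plasma / bp_ratio
  if (cl_blood >= q_hep_blood) {
    stop(sprintf(paste0(
      "invert_well_stirred(): target plasma clearance %.4g L/h implies blood ",
      "clearance %.4g L/h at or above the hepatic blood flow (%.4g L/h); ",
      "the well-stirred model cannot reach flow-limited targets"),
      cl_plasma, cl_blood, q_hep_blood))
  }
  fu_b <- fu / bp_ratio
  q_hep_blood * cl_blood / (q_hep_blood - cl_blood) / fu_b
}

#' Quasi-steady-state concentration from a zero-order input
#'
#' When the input rate varies slowly relative to the elimination half-life
#' (true for the implant after the first weeks), plasma concentration is
#' input rate / clearance. Converts ug/day and L/h to pg/mL.
#'
#' @param release Input rate, ug/day (>= 0).
#' @param cl_plasma Plasma clearance, L/h (> 0).
#' @return Concentration, pg/mL.
#' @examples
#' steady_state_conc(40, 5.86)  # ~284 pg/mL
#' @export
steady_state_conc <- function(release, cl_plasma) {
  stopifnot(all(release >= 0))
  if (any(cl_plasma <= 0)) {
    stop("steady_state_conc(): plasma clearance must be positive")
  }
  # ug/day -> pg/h: * 1e6 / 24 ; L/h -> mL/h: * 1000
  release * 1e6 / 24 / (cl_plasma * 1000)
}
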