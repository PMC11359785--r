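# Closed-form solutions of the linear two-compartment disposition model.
# Shared by the PBPK analytic path and the mixed-effects reference model.
# Internal units: amounts ug, volumes L, times h, concentrations ug/L
# (1 ug/L = 1000 pg/mL).

# Macro-constants: hybrid rate constants (alpha > beta) and the unit-impulse
# central-concentration response h(t) = c1*exp(-alpha t) + c2*exp(-beta t).
twocpt_macro <- function(cl, vc, vp, q) {
  stopifnot(cl >= 0, vc > 0, vp > 0, q > 0)
  k10 <- cl / vc
  k12 <- q / vc
  k21 <- q / vp
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  denom <- alpha - beta
  list(alpha = alpha, beta = beta, k21 = k21,
       c1 = (alpha - k21) / (vc * denom),
       c2 = (k21 - beta) / (vc * denom),
       vc = vc)
}

# Central concentration after an IV bolus at t = 0.
twocpt_conc_iv_bolus <- function(t, dose, macro) {
  out <- dose * (macro$c1 * exp(-macro$alpha * pmax(t, 0)) +
                 macro$c2 * exp(-macro$beta * pmax(t, 0)))
  out[t < 0] <- 0
  out
}

# Central concentration after a single first-order-absorbed oral dose at
# t = 0 with systemic availability f.
twocpt_conc_oral <- function(t, dose, f, ka, macro) {
  a <- macro$alpha; b <- macro$beta; k21 <- macro$k21; vc <- macro$vc
  # guard exact degeneracy ka == alpha or beta (measure-zero; nudge)
  if (abs(ka - a) < 1e-10 * ka) ka <- ka * (1 + 1e-8)
  if (abs(ka - b) < 1e-10 * ka) ka <- ka * (1 + 1e-8)
  tt <- pmax(t, 0)
  coef <- f * dose * ka / vc
  out <- coef * ((k21 - a) / ((ka - a) * (b - a)) * exp(-a * tt) +
                 (k21 - b) / ((ka - b) * (a - b)) * exp(-b * tt) +
                 (k21 - ka) / ((a - ka) * (b - ka)) * exp(-ka * tt))
  out[t < 0] <- 0
  out
}

# Integral of (a0 + slope*(tau - t0)) * exp(-lambda*(t - tau)) dtau over
# tau in [t0, min(t1, t)], vectorised over t. Building block of the exact
# response to a piecewise-linear zero-order input.
exp_seg_integral <- function(t, t0, t1, a0, slope, lambda) {
  u1 <- pmin(t1, t)
  active <- t > t0
  s0 <- t - u1          # nearest edge of the segment, in elapsed time
  s1 <- t - t0          # farthest edge
  e0 <- exp(-lambda * s0)
  e1 <- exp(-lambda * s1)
  i_const <- (e0 - e1) / lambda
  j <- (s0 / lambda + 1 / lambda^2) * e0 - (s1 / lambda + 1 / lambda^2) * e1
  out <- (a0 + slope * (t - t0)) * i_const - slope * j
  out[!active] <- 0
  out
}

# Exact central concentration for a piecewise-linear input rate into the
# central compartment. `segments` is a 4-column matrix (t0, t1 in h,
# r0 in ug/h at t0, slope in ug/h per h); flat tails use slope 0.
twocpt_conc_zero_order <- function(t, segments, macro) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(segments))) {
    t0 <- segments[i, 1]; t1 <- segments[i, 2]
    r0 <- segments[i, 3]; sl <- segments[i, 4]
    out <- out +
      macro$c1 * exp_seg_integral(t, t0, t1, r0, sl, macro$alpha) +
      macro$c2 * exp_seg_integral(t, t0, t1, r0, sl, macro$beta)
  }
  out
}

input_segment <- function(t0, t1, r0, slope = 0) {
  matrix(c(t0, t1, r0, slope), nrow = 1,
         dimnames = list(NULL, c("t0", "t1", "r0", "slope")))
}

# Piecewise-linear segment table (in hours, ug/h) for a release schedule,
# including the flat plateaus before the first and after the last knot.
release_segments <- function(schedule, t_max_h) {
  kn <- schedule$knots
  th <- kn$month * HOURS_PER_MONTH
  r <- kn$rate_ug_day / 24
  n <- nrow(kn)
  t0 <- c(0, th)
  t1 <- c(th, max(t_max_h, th[n]) + 1)
  r0 <- c(r[1], r)
  slope <- c(0, if (n > 1) diff(r) / diff(th), 0)
  keep <- t0 < t_max_h
  cbind(t0 = t0, t1 = t1, r0 = r0, slope = slope)[keep, , drop = FALSE]
}

HOURS_PER_MONTH <- 365.25 * 24 / 12
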