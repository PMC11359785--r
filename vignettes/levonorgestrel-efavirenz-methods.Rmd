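---
title: "A minimal PBPK model of the levonorgestrel implant under CYP3A4 induction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal PBPK model of the levonorgestrel implant under CYP3A4 induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lngpbpk)
```

## The problem

Subdermal levonorgestrel implants provide up to five years of contraception
from a slowly declining zero-order release of hormone. Efavirenz, a
first-line antiretroviral, induces CYP3A4 and thereby accelerates
levonorgestrel metabolism, lowering its plasma concentrations and
potentially compromising contraceptive efficacy. Because the interaction is
hard to study clinically at scale, a mechanistic simulation is the
practical way to compare mitigation strategies: doubling the implant dose
(300 mg, four rods), lowering the efavirenz dose (400 mg daily), or both.

`lngpbpk` implements a deliberately minimal physiologically-based model of
this system: lumped two-compartment disposition, well-stirred hepatic
elimination, gut-wall first pass for oral dosing, and a reduced
dose-to-exposure description of the perpetrator feeding an Emax induction
curve. Everything the package predicts is driven by a small set of clinical
reference values through retrograde calibration, so the model is
transparent about which knobs produce which outputs.

## Model structure and assumptions

**Disposition.** Levonorgestrel kinetics are linear: a central compartment
(volume `vc_fraction * Vss * BW`) exchanging with a peripheral compartment
via intercompartmental clearance `Q_inter` = 10.2 L/h, with total
`Vss` = 2.27 L/kg and a typical body weight of 67.3 kg (women of
reproductive age). Elimination is exclusively hepatic — levonorgestrel has
no meaningful renal pathway — and is applied to the central compartment.

**Hepatic clearance.** The well-stirred liver model converts unbound
whole-liver intrinsic clearance to plasma clearance:

$$CL_b = \frac{Q_h \, f_{u,b} \, CL_{int,u}}{Q_h + f_{u,b}\, CL_{int,u}},
\qquad f_{u,b} = \frac{f_u}{B\!/\!P}, \qquad CL_p = CL_b \cdot B\!/\!P$$

with fraction unbound in plasma $f_u$ = 0.013, blood-to-plasma ratio
$B/P$ = 0.671, and hepatic blood flow $Q_h$ = 87 L/h (about 1.45 L/min,
an adult female liver). At the calibrated operating point the hepatic
extraction ratio is about 0.10, so the model is mostly
capacity-limited but retains a visible flow-limited component — this
matters for the binding sweep below.

**Implant input.** Release is zero-order and time-varying, given by a knot
table (100 µg/day at month 1 declining to 40 by one year, 30 by three
years, 25 by five) with linear interpolation between knots and flat
extrapolation on both sides. The table rates are amounts reaching the
systemic circulation, so implant input enters the central compartment with
no first-pass loss. A 300 mg implant is the same schedule scaled by two.

**Oral input.** First-order absorption (`ka` = 1/h) with systemic
availability $F = F_a \cdot F_g \cdot F_h$, where $F_h = 1 - E$ comes from
the well-stirred extraction and $F_g$ is the gut-wall availability.
`ka` and `Fa` = 1 shape only the absorption transient; they do not affect
steady state or AUC-derived quantities.

**Solution methods.** The system is linear, so the package carries both a
full ODE integration (`deSolve::lsoda`, rtol 1e-8, atol 1e-10) and exact
closed forms: biexponential IV response, the standard three-exponential
oral solution, and the convolution of the biexponential unit response with
the piecewise-linear implant input. The implant's release changes on a
time scale of months while the elimination half-life is below a day, so
concentrations sit at quasi-steady state (rate/clearance) from month one
onward; the tests verify the ODE, the exact convolution, and rate/CL agree
within 2% at months ≥ 6. Scenario runs use the quasi-steady-state
evaluation by default because it is exact enough and makes population
sweeps cheap.

## Retrograde calibration

No published in-vitro assay pins down levonorgestrel's hepatic intrinsic
clearance, so the package back-solves it from whole-body reference values,
mirroring how such gaps are filled in practice:

1. **`retrograde_clint()`** inverts the well-stirred equation in closed
   form so the forward model reproduces the reference baseline clearance
   CL = 5.86 L/h exactly. With the default binding parameters this gives
   $CL_{int,u} \approx 501$ L/h. A grid-scan mode reproduces the same
   answer by sensitivity scanning, for parity with how such calibrations
   are usually described.
2. **`calibrate_gut()`** sets $F_g = F/(F_a F_h)$ so oral bioavailability
   matches the reference F = 0.84, giving $F_g \approx 0.934$ and
   CL/F ≈ 6.98 L/h.
3. **`calibrate_induction()`** converts the observed implant concentration
   ratios under efavirenz (0.68 at 600 mg daily, 0.72 at 400 mg) into
   required net fold-increases of hepatic CYP3A4 activity and solves an
   Emax curve through the two points.

Step 3 deserves a note, because it is where a design choice was genuinely
open. At quasi-steady state the concentration ratio equals
$CL_0 / CL'$. A common shortcut treats clearance as proportional to
intrinsic clearance, giving the required fold directly as
$(1/\text{ratio} - (1 - f_m))/f_m$ with $f_m$ = 0.16 the CYP3A4 share of
hepatic elimination. At 10% extraction that shortcut is visibly wrong:
feeding its fold (3.94) back through the well-stirred model predicts a
ratio of 0.71, not 0.68, and inflates the binding-sweep totals by ~5%.
The package therefore inverts the well-stirred model exactly — induced
plasma clearance $CL_0/\text{ratio}$, inverted to the induced
intrinsic-clearance multiplier, then
$I = (m - (1-f_m))/f_m$ — giving $I_{600} = 4.45$ and $I_{400} = 3.82$,
and solves the 2×2 Emax system in closed form
($Ind_{max} \approx 6.20$, $E_{600}/IndC_{50} \approx 1.26$). The linear
shortcut is retained as `method = "linear"` for comparison; its constants
($Ind_{max} \approx 5.07$, $E_{600}/IndC_{50} = 1.38$) are frozen in the
test suite as a cross-check of the solver algebra.

The reference set also reports an induced-state clearance pair
(CL = 10.10 L/h, CL/F = 18.95 L/h). In a linear model those values are
mutually inconsistent with the 0.68 concentration ratio (10.10/5.86 = 1.72
would imply a ratio of 0.58), and the concentration-ratio family is
self-consistent with the implant predictions and the binding sweep, so the
ratios are the default calibration target. `target = "cl_pair"` lets users
explore the other reading; the package does not silently reconcile the two.

The gut wall is treated as fully CYP3A4-mediated: induction shrinks
availability by the competing-rates inversion
$F_g' = F_g / (F_g + (1-F_g)\,\text{fold})$, with the gut fold equal to
the liver fold by default (same driving exposure, same Emax curve). Gut
induction affects only oral dosing; implant input bypasses it, which is
why the implant interaction (~1.5-fold clearance increase) is much milder
than the oral one.

## The perpetrator model

Efavirenz is reduced to a linear dose-to-exposure map: exposure in units
of the 600 mg steady-state reference, so 400 mg → 2/3 and 4800 mg → 8.
This is defensible because both drugs have half-lives beyond 36 h and flat
within-day profiles; genetic variation in efavirenz metabolism is
represented by the same axis (an `exposure_multiplier`), since a slow
metabolizer at 600 mg and a normal metabolizer at a higher dose see the
same average exposure. Efavirenz autoinduction is absorbed into the
exposure constant rather than modeled. The induction fold is
$1 + Ind_{max} E/(IndC_{50}+E)$ — monotone, saturating, so successively
higher exposures buy less and less additional induction. A turnover mode
(`enzyme_turnover()`, kdeg 0.0193/h ≈ 36 h enzyme half-life) describes the
approach to induced steady state; at month-scale sampling it is
indistinguishable from the static mode (>96% of the effect within a week),
which is why static application is the default even though efavirenz
starts on the day of implant placement in the simulated scenarios.

What this reduced model does **not** capture: the perpetrator's own
nonlinear kinetics across the exposure range. The exposure-sweep outputs
are therefore treated as qualitative (monotone, saturating) rather than
quantitative; the package's sweep yields concentration drops of ~13%/16%
at 4-fold/8-fold exposure where a full perpetrator model yields somewhat
larger ones. The tests assert the shape, not those percentages.

## The binding sweep

Displacement of levonorgestrel from plasma proteins (efavirenz competes
for albumin) is explored by varying $f_u$ over 0.6–2.6% — half to twice
the population value — holding unbound intrinsic clearance fixed, since
binding changes do not alter the enzymes. Two opposing effects follow from
the well-stirred model: clearance rises with $f_u$ (total concentration
falls almost proportionally), while unbound concentration
$f_u \times$ total rises only mildly because the flow-limited component
damps the clearance gain. At the default hepatic blood flow of 87 L/h,
doubling $f_u$ from 1.3% to 2.6% under 300 mg + efavirenz 600 mg moves
totals from ~387 to ~222 pg/mL with a ~15% rise in unbound concentration —
the flow value was chosen (once) as the standard adult-female hepatic
blood flow that places the model in this regime; with a much larger flow
the model would be purely capacity-limited and totals would halve exactly.

## The reference mixed-effects model

The whole-body reference values come, in the original analysis, from a
two-compartment mixed-effects model pooling mean concentration–time data
from four trials (single IV 0.25 mg; single oral 0.25 mg; two oral
0.75 mg doses 12 h apart, with and without efavirenz; 150 mg implant over
48 weeks, with and without efavirenz). Those digitized means are not
redistributable, so the package implements the model itself
(`predict_means()`, `fit_mem()`) and exercises it on synthetic data with
the same statistical structure: a study-level random effect on F —
additive on the logit scale, a choice made here to keep F in (0,1) since
the scale is not otherwise specified — and proportional residual error on
means, each mean treated as a single observation (study sizes being
unavailable, a documented limitation).

The marginal likelihood integrates the scalar random effect per study by
adaptive Gauss–Hermite quadrature (9 nodes, recentred at the conditional
mode and rescaled by its curvature; nodes from a Golub–Welsch
eigendecomposition). Studies without an oral arm are independent of the
random effect and contribute their conditional likelihood directly. A
brute-force trapezoid integration over a wide grid serves as the
cross-check; the two agree to ~1e-5 log-units on test instances.
Optimization is quasi-Newton (`nlminb`) on log/logit-transformed
parameters with seeded jittered restarts, initial values at the reported
estimates; standard errors come from the numeric Hessian by the delta
method. Because only one IV arm identifies F, identifiability is enforced
as a precondition (at least one IV or implant arm), and absorption-phase
parameters (`ka`, lag behaviour, the central-volume split) are declared
defaults rather than inferred — mean data at these designs inform them
weakly.

The parameter-recovery experiment in the acceptance suite generates 50
replicate four-trial datasets at the reported truth (omega_f 0.3,
sigma_prop 0.1 — realistic invented values, stated here once) and refits;
median clearance bias is required below 5% and the induced/baseline
clearance ratio within 10%. Problem sizes (7 arms, ~70 observations,
50 replicates, single restart per replicate from the truth-anchored
inits) were chosen so the whole experiment runs in about two and a half
minutes.

## Virtual populations

`gen_population()` draws median-preserving log-normal variability around
the calibrated typical subject: 30% CV on intrinsic clearance, 15% on
hepatic blood flow, 20% on Vss, 15% on body weight about a 67.3 kg
median. Only the mean weight is reported for the study population; the
CVs are this package's choices, fixed once at magnitudes conventional for
adult pharmacokinetics. Fraction unbound is fixed by default — binding
variation is the sweep's job, and conflating the two would blur its
interpretation. Median preservation means the population median
concentration tracks the typical subject (verified at n = 2000 within 3%,
and at the n = 200 study size with the suite's fixed seed); dispersion,
not location, is what the population adds. All draws flow through one
mandatory seed; there is no hidden global state beyond R's seeded RNG.

What the generator does *not* emulate: correlation between parameters
(weight-clearance allometry, flow-volume coupling), non-log-normal tails,
within-subject variation over five years, or assay noise in observed
concentrations. Passing population tests therefore demonstrate internal
consistency of the simulator, not calibration of its variability against
real between-woman spread.

## Numerical choices and degenerate inputs

* Closed-form inversions are preferred to iterative scans everywhere a
  closed form exists; the scan modes exist for documentation parity and
  agree to 1e-6 relative.
* Integrator tolerances rtol 1e-8 / atol 1e-10; integrator failure raises
  an error rather than returning a truncated profile.
* Flow-limited calibration targets (CL ≥ Q·B/P), oral F targets above
  Fa·Fh, concentration-ratio pairs inconsistent with a saturating Emax
  curve, non-positive doses, and negative times are all rejected with
  diagnostics naming the offending constraint.
* The oral closed form nudges `ka` by 1e-8 relative if it coincides with a
  disposition exponent (a measure-zero degeneracy).
* `vc_fraction` defaults to 0.3 of Vss; it shapes transients only and is
  configurable. Tests that depend on steady state are insensitive to it.
* Residual noise in the trial-mean generator is truncated by redrawing the
  rare multiplier below zero, keeping concentrations positive without
  biasing the common case.

## Worked headline numbers

```{r}
cal <- calibrate_baseline()
sc <- run_scenarios(cal)
subset(sc, month %in% c(12, 36, 60) & scenario_id == 1,
       c(month, release_ug_day, cl_L_per_h, total_pg_per_ml))
subset(sc, month == 12, c(scenario_id, lng_mg, efv_mg, ratio_to_control))
fs <- run_fu_sweep(cal)
subset(fs, fu %in% c(0.013, 0.026))
attr(cal$ind, "fold600")
run_exposure_sweep(cal)[, c("efv_mg", "fold", "ratio_to_reference")]
# induced-state oral CL/F implied by the ratio-calibrated model
pk_ind <- apply_induction(cal$pk, attr(cal$ind, "fold600"))
oral_bioavailability(pk_ind, cal$subject)$cl_over_f
```

The control implant sits at ~284 pg/mL at one year, ~213 at three and
~178 at five; efavirenz 600/400 mg lowers concentrations to 68%/72% of
control, the doubled implant restores 136%/144%; the binding sweep moves
totals 387 → 222 pg/mL as $f_u$ doubles while unbound rises ~15%; and the
calibrated net hepatic CYP3A4 fold at the 600 mg reference exposure is
4.45. `scripts/acceptance.R` recomputes exactly these quantities from a
fresh calibration.

## Known limitations

* The model is minimal by design: no multi-organ distribution, no renal
  pathway, no SHBG-specific nonlinear binding (fraction unbound is an
  exogenous dial, not an equilibrium computed from displacement kinetics).
* The perpetrator is an exposure axis, not a drug model; exposure-sweep
  magnitudes are qualitative.
* The induced-state oral CL/F implied by the calibrated model (computed in
  the chunk above, ~13 L/h) is
  smaller than the reported 18.95 L/h, a direct consequence of privileging
  the concentration-ratio calibration over the inconsistent induced
  clearance pair; both readings cannot hold at once in a linear model.
* Mean-level fitting with unit weights cannot recover the precision of an
  individual-data analysis; recovery tests bound bias, not efficiency.
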