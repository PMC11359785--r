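# lngpbpk

A minimal physiologically-based pharmacokinetic (PBPK) simulator of the
drug–drug interaction between the levonorgestrel contraceptive implant and
the CYP3A4 inducer efavirenz, for pharmacometricians evaluating
dose-mitigation strategies (doubling the implant to 300 mg, lowering
efavirenz to 400 mg daily, or both) and the secondary roles of plasma
protein binding and efavirenz exposure variability.

## The model

Levonorgestrel disposition is a linear two-compartment system with
exclusively hepatic elimination through the well-stirred liver model,

```
CL_b = Q_h · f_u,b · CL_int,u / (Q_h + f_u,b · CL_int,u),   f_u,b = f_u / (B/P)
```

fed by a zero-order, time-varying implant release schedule (100 µg/day at
month 1 declining to 25 µg/day at five years; input directly systemic), or
by oral/IV dosing with `F = Fa · Fg · Fh`. The unobservable whole-liver
unbound intrinsic clearance `CL_int,u` and gut availability `Fg` are
*retrogradely calibrated* — back-solved in closed form so the forward model
reproduces clinical reference values (baseline CL 5.86 L/h, oral F 0.84).
Efavirenz is reduced to a linear dose→exposure axis driving an Emax
induction curve, `fold = 1 + Ind_max·E/(IndC50 + E)`, itself calibrated
from the observed implant concentration ratios (68% of control at 600 mg
daily, 72% at 400 mg) acting on the CYP3A4 share (`fm ≈ 16%`) of hepatic
elimination. A two-compartment mixed-effects reference model (study-level
random effect on F, proportional residual error, adaptive Gauss–Hermite
marginal likelihood) and seeded synthetic-data generators make every part
testable without any external data.

## Worked example

```r
library(lngpbpk)

cal <- calibrate_baseline()          # retrograde CLint,u + Fg + induction
sc  <- run_scenarios(cal)            # five mitigation scenarios, months 0-60

subset(sc, month == 12,
       c(scenario_id, lng_mg, efv_mg, total_pg_per_ml, ratio_to_control))
#>  scenario_id lng_mg efv_mg total_pg_per_ml ratio_to_control
#>            1    150     NA        284.4141             1.00
#>            2    150    600        193.4016             0.68
#>            3    150    400        204.7782             0.72
#>            4    300    600        386.8032             1.36
#>            5    300    400        409.5564             1.44
```

At one year the 150 mg implant alone yields ~284 pg/mL; co-administered
efavirenz 600 mg cuts that to 68% (~193 pg/mL), while the doubled 300 mg
implant under the same efavirenz dose restores 136% of control. The
protein-binding sweep (`run_fu_sweep`) shows that doubling the fraction
unbound from 1.3% to 2.6% nearly halves *total* concentrations
(387 → 222 pg/mL at 300 mg + efavirenz 600 mg) while raising *unbound*
concentrations only ~15%; the exposure sweep (`run_exposure_sweep`) shows
the induction effect saturating at high efavirenz exposure. Population
runs (`gen_population`, 200 virtual women with log-normal variability) add
5th–95th percentile bands around the typical subject.

A thin command-line wrapper with subcommands `calibrate`, `scenarios`,
`sweep-fu`, `sweep-exposure`, `memfit` and `generate` lives at
`inst/cli/lngpbpk-cli.R`.

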