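# inhibkin

Profiling small-molecule inhibitors from plate-reader assay data: enzyme
inhibition kinetics for cholinesterases (Ellman assay) and BACE-1
(fluorogenic substrate), and thioflavin-T quantification of amyloid-beta
self-aggregation. The package takes raw kinetic traces or reduced velocity
tables and produces, per compound and target, the three numbers a
medicinal-chemistry campaign reports: **IC50**, the **inhibition
mechanism**, and the apparent **inhibition constant Ki**.

## What it computes

Velocities follow the Michaelis–Menten law, v = Vmax·S/(Km + S), fitted
either by nonlinear least squares or by the Lineweaver–Burk
double-reciprocal line. Fitting the inhibited panel at each dose [I] gives
primed parameters (K'm, V'max), and the shift pattern identifies the
mechanism: Vmax↓ with Km unchanged (noncompetitive), Km↑ with Vmax
unchanged (competitive), both ↓ with Km/Vmax preserved (uncompetitive),
both shifted with the ratio broken (mixed). The apparent inhibition
constant at each dose is

    K'i = V'max [I] / (Vmax − V'max)      noncompetitive
    K'i = K'm  [I] / (K'm − Km)           competitive
    K'i = K'm  [I] / (Km − K'm)           uncompetitive
    mixed: mean of the first relation with the second or third,
           keyed to the sign of the Km shift

and the per-dose values are averaged into a single apparent Ki. IC50s come
from straight-line fits on a semilogarithmic plot, in either of two
dialects (residual vs log-dose, or log-residual vs dose); fits outside the
tested dose range are flagged as censored. A synthetic-data generator with
known ground truth (general modifier equation for velocities, logistic
inhibition law for ThT plateaus) backs every recovery claim.

## Worked example

Simulate a noncompetitive inhibitor (true Ki = 12 µM, 2% replicate noise)
at the standard design — substrate 80–500 µM, doses 2.5–10 µM, triplicates
— and profile it:

```r
library(inhibkin)

tr <- inhibition_truth("noncompetitive", Km = 100, Vmax = 10, Ki_c = 12,
                       noise_cv = 0.02, seed = 42)
panel <- simulate_velocity_panel(tr)

prof <- profile_inhibition(panel)
prof
#> <inhibition_profile> noncompetitive (nonlinear fits)
#> <ki_estimate> Ki = 11.7765 +/- 0.277 uM (n = 3)

prof$fits[["0"]]   # uninhibited baseline
#> <mm_fit nonlinear> Km = 96.185 +/- 4.48 uM, Vmax = 9.97393 +/- 0.144, gof = 0.9901 (n = 15, I = 0 uM)
prof$fits[["10"]]  # at 10 uM inhibitor: Vmax halves, Km stays
#> <mm_fit nonlinear> Km = 94.4462 +/- 4.69 uM, Vmax = 5.36347 +/- 0.0817, gof = 0.9885 (n = 15, I = 10 uM)

prof$ki$per_conc   # per-dose apparent Ki, pooled above
#>   I_uM       Ki
#> 1  2.5 12.09584
#> 2  5.0 11.60038
#> 3 10.0 11.63325
```

The classifier reads the halved Vmax at unchanged Km as noncompetitive,
applies the matching Ki relation at each dose, and pools to 11.8 ± 0.3 µM
against the true 12 µM. An IC50 from a hyperbolic residual law sampled
log-symmetrically about its midpoint is recovered exactly:

```r
I <- c(1.25, 2.5, 5, 10, 20)
fit_ic50(data.frame(I_uM = I, residual = 100 / (1 + I / 5)),
         "residual_vs_log_conc")
#> <dose_response_curve residual_vs_log_conc> IC50 = 5 uM, r2 = 0.9981 (n = 5)
```

The ThT chain goes from raw scans to an IC50 row the same way
(`simulate_tht_assay()` → `reduce_tht_scans()` → `fit_ic50()`), and
`run_profiling()` drives any number of assays from a YAML config to a
deterministic CSV/JSON report; `inst/cli/inhibkin.R` wraps the same
functions as shell subcommands (generate, reduce, fit, mechanism, ic50,
validate, profile).

## Layout

- `R/` — generators (`simulate.R`), trace reduction (`trace.R`), MM
  fitting (`mm-fit.R`), mechanism and Ki (`mechanism.R`), IC50
  (`dose-response.R`), I/O and validation (`io.R`), orchestration
  (`profile.R`).
- `tests/testthat/` — unit, property and end-to-end recovery tests.
- `vignettes/inhibition-profiling.Rmd` — the methods notes: model
  assumptions, parameter defaults, numerical conventions, and known
  estimator biases (including why the log-residual IC50 dialect
  overshoots on sparse grids).
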