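---
title: "Profiling enzyme inhibitors and aggregation blockers with inhibkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling enzyme inhibitors and aggregation blockers with inhibkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibkin)
```

# The measurement chain

inhibkin implements the analytical chain used to characterise multi-target
inhibitors in vitro against cholinesterases (AChE, BuChE; Ellman
thiocholine/DTNB readout at 412 nm), BACE-1 (FRET peptide substrate) and
amyloid-beta self-aggregation (thioflavin-T endpoint fluorescence). Three
quantities summarise a compound: the IC50 against each target, the
inhibition mechanism, and the apparent inhibition constant Ki. Each is
derived from plate-reader primary data through the stages below, and every
stage is exercised end-to-end on synthetic data with known ground truth.

## Initial rates from kinetic traces

The enzymatic readout is a progress curve: signal versus time, linear at
first and decelerating as substrate is consumed. The initial rate $v_0$ is
the slope of the initial linear portion. `extract_initial_rate()` selects
the longest prefix window — anchored at the first sample, optionally capped
(e.g. at 30 min for BACE-1-style kinetics) — whose ordinary least-squares
fit achieves $r^2 \ge$ `r2_threshold` (default 0.99, minimum 5 samples),
and reports the slope, $r^2$ and the slope's standard error. Prefix
anchoring is deliberate: the quantity of interest is the *initial* rate, so
a best-window-anywhere search is not offered as a default behaviour.

Two numerical conventions matter. A perfectly flat window is defined to
have $r^2 = 1$ and $v_0 = 0$ (avoiding 0/0 in the variance ratio), so
zero-activity wells reduce cleanly. And the $r^2 \ge 0.99$ criterion is a
*tolerance for bend*: on a trace whose curvature starts at time $t_c$, the
longest window satisfying it typically overruns $t_c$ by a few samples and
depresses the slope by several percent — this is a property of any
variance-ratio criterion, not of the implementation. Users who need
sub-percent accuracy should either raise `r2_threshold` (0.9999 confines
the window to the linear portion in our synthetic checks) or cap
`max_window` at a time known to be within the linear regime, which recovers
the true slope exactly on noiseless traces.

## Plateau fluorescence from ThT scans

Fibril formation is quantified by the plateau of a 300 s thioflavin-T
fluorescence scan, averaged over at least two minutes of plateau.
`plateau_mean()` searches suffix windows (longest first, minimum span
`min_span` = 120 s) and accepts the first whose fitted slope is not
significantly different from zero (two-sided normal test of slope/se at
`slope_alpha` = 0.05); a genuinely flat noiseless window passes by the
zero-variance convention above. Because an $\alpha = 0.05$ test falsely
rejects about 5% of genuinely flat noisy scans, the batch-level reducer
`reduce_tht_scans()` falls back to averaging the trailing `min_span` window
for such scans and marks them, rather than failing a whole plate; the
single-scan function keeps the strict error contract.

Residual self-aggregation is the background-subtracted sample plateau as a
percentage of the background-subtracted uninhibited control,
$100\,(F_s - F_b)/(F_c - F_b)$, clamped below at zero; values above 100%
(signal enhancement) are kept but flagged.

## Michaelis–Menten fitting

`fit_mm_nonlinear()` fits $v = V_{max} S/(K_m + S)$ by unweighted
Levenberg–Marquardt least squares; `fit_mm_lineweaver_burk()` fits the
double-reciprocal line $1/v$ on $1/S$ and transforms back. Replicates enter
as individual points; weighting is deliberately plain least squares in both
routes. Initialisation is parameter-free ($V_{max}^0 = 1.2 \max v_0$,
$K_m^0$ = the substrate concentration whose rate is nearest $V_{max}^0/2$)
with convergence at a relative step below $10^{-10}$ or 500 iterations.
Saturated panels (all rates equal) drive $K_m$ to the boundary and are
reported as fit failures carrying the last iterate, not silently returned.
On noiseless data both routes agree with the truth to floating-point
precision; on noisy data the reciprocal transform amplifies low-rate noise,
so the nonlinear route is the pipeline default and every result records
which method produced it.

## Mechanism classification

The inhibited panel at each dose $I$ is fitted separately, giving
$K'_m, V'_{max}$, and the shift pattern against the uninhibited fit is
mapped to a label: $V_{max}$ down with $K_m$ unchanged is noncompetitive;
$K_m$ up with $V_{max}$ unchanged is competitive; both down with the
$K_m/V_{max}$ ratio preserved is uncompetitive; $K_m$ shifted and
$V_{max}$ down with the ratio broken is mixed; any other pattern (e.g.
$V_{max}$ rising) is undetermined — a value, not an error.

A parameter counts as *changed* only when its relative shift exceeds
`rel_tol` (default 0.10) **and** the shift is significant at `alpha`
(default 0.05) under a two-sample z-test on the fitted values. Requiring
both conditions is the package's own screen (the assay protocol states no
criterion): the significance condition stops large-but-noisy shifts from
being chased, while the relative-tolerance condition stops precisely
measured but negligible shifts from breaking a call. With tolerance alone,
or significance alone, the false-change rate at realistic noise (2%
replicate CV) would be dominated by the uninhibited baseline fit, which is
shared by all comparisons.

Per-compound labels are a consensus across doses: majority vote over the
per-dose calls (ignoring undetermined), ties resolved in favour of the
highest dose, where the parameter shifts are largest relative to their
uncertainty.

## Apparent Ki

At each dose the apparent inhibition constant is computed from the
parameter shifts:

* noncompetitive: $K'_i = V'_{max} [I] / (V_{max} - V'_{max})$;
* competitive: $K'_i = K'_m [I] / (K'_m - K_m)$;
* uncompetitive: $K'_i = K'_m [I] / (K_m - K'_m)$;
* mixed: the mean of the noncompetitive relation with the competitive one
  (when $K'_m$ rose) or the uncompetitive one (when $K'_m$ fell). The sign
  of the $K_m$ shift is the only information that distinguishes the two
  pairings, so it keys the choice.

The noncompetitive and uncompetitive relations are exact inverses of their
generating laws: for noncompetitive truth $V'_{max} = V_{max}/(1 + I/K_i)$
and relation 1 returns $K_i$ at every dose; for uncompetitive truth
$K'_m = K_m/(1 + I/K_i)$ and relation 3 does the same. The competitive
relation as stated carries $K'_m$ — not $K_m$ — in its numerator, and for
exact competitive truth ($K'_m = K_m(1 + I/K_i)$) it algebraically returns
$K_i + I$ rather than $K_i$. We implement the relation exactly as stated
and document the property (it is verified as an identity in the test
suite); an `equation_mode = "classical"` option substitutes $K_m$ in the
numerator, which recovers $K_i$ exactly, but it is never the default. The
per-dose values are pooled by arithmetic mean and sample standard
deviation (`pooled_ki()`).

## IC50 estimation

IC50 is interpolated from a straight-line fit in one of two
semilogarithmic dialects, both first-class because assay write-ups use
both:

* `residual_vs_log_conc` (enzyme default): residual % on $\log_{10} I$;
  $IC_{50} = 10^{(50 - b_0)/b_1}$.
* `log_residual_vs_conc` (ThT default): $\log_{10}$(residual %) on $I$;
  $IC_{50} = (\log_{10} 50 - b_0)/b_1$.

The $I = 0$ control is used only for normalisation, never in the fit. A
fitted IC50 outside the tested dose range is reported but flagged censored,
with the `IC50` field carrying the nearest tested bound and the raw
interpolate kept alongside — extrapolated values must be representable
because real assays do report IC50s above their top tested dose. A slope of
the wrong sign yields a flagged no-inhibition result rather than an error.

Neither dialect is a logistic fit, and that matters on sparse grids: for a
hill-1 logistic with midpoint 100 µM sampled at {24, 120, 240} µM,
$\log_{10}$(residual) is convex in $I$ and the log-residual dialect's
straight line crosses 50% at 117.3 µM even at zero noise — a deterministic
17% overestimate that no amount of replication removes (the test suite
asserts this value as a documented property). The conventional dialect is
far less biased on the same points. We keep the log-residual dialect as the
ThT default because it is the transform the assay protocol specifies, and
every report row names the dialect it used; a 4PL fit is deliberately out
of scope for the default path.

# The synthetic-data generator

All recovery claims are calibrated against `simulate_velocity_panel()`,
`simulate_progress_trace()` and `simulate_tht_assay()`, whose defaults are
the study conditions of the assays the package targets:

* substrate grid {80, 125, 200, 330, 500} µM (the Ellman-assay working
  range) and inhibitor doses {0, 2.5, 5, 10} µM for enzyme panels;
* ThT doses {0, 24, 120, 240} µM, 300 s scans at 1 Hz, with a dye-only
  background scan;
* 3 replicates per condition, mirroring triplicate determinations.

Velocities come from the general modifier equation
$v = V_{max} S / \big(K_m (1 + I/K_{ic}) + S (1 + I/K_{iu})\big)$, which
contains all four pure mechanisms as limiting cases. Velocity noise is
multiplicative Gaussian (CV-parameterised), matching the roughly
proportional scatter of enzymology replicates; trace and scan noise is
additive Gaussian. The replicate CV is a free simulation parameter — the
recovery tests fix it at 2%, a value typical of well-behaved
spectrophotometric replicates. Progress-curve curvature is a
saturating-exponential approach to plateau with a continuous derivative at
the onset and time constant one third of the remaining duration: the assays
only assert an initial linear portion, so any smooth decelerating form
serves, and this one needs no extra parameters.

What the generator does *not* emulate: nucleation–elongation fibrillation
kinetics (the ThT measurement is an endpoint after incubation, so only the
endpoint level is modelled), instrument drift or photobleaching, inner
filter effects, outliers and well failures, and dose-dependent replicate
variance. Passing recovery tests therefore demonstrate correctness of the
analysis chain under clean, well-specified noise — not robustness to every
pathology of real plates.

# Recovery behaviour at the study design

Problem sizes were chosen to characterise the estimators tightly while
keeping the whole suite fast: 200 seeded panels per mechanism (each 5
substrate × 4 dose × 3 replicates, 2% CV) for classification accuracy and
pooled-Ki recovery, and 200 seeded scan sets for the ThT chain. At that
design the consensus classifier recovers noncompetitive, uncompetitive and
competitive truths in ≥95% of panels and mixed truths ($K_{ic}$ = 5,
$K_{iu}$ = 20 µM) in ≥90%; the pooled Ki for a 12 µM noncompetitive truth
has median within 10% of truth; and the ThT chain reproduces the
log-residual dialect's deterministic 17% bias discussed above. The
`scripts/acceptance.R` script regenerates all of these numbers from
scratch.

# Degenerate inputs and tie-breaks

* Flat signal: $r^2$ defined as 1 (plateau passes, rate is 0).
* Saturated velocity panels: boundary-pinned fit failure, surfaced with
  the last iterate.
* Non-positive rates: rejected by the reciprocal route (listing rows),
  warned about elsewhere.
* Residual ≤ 0 under a log transform: excluded with a warning.
* Mechanism ties: single-parameter patterns (competitive, noncompetitive)
  take precedence over mixed; consensus ties go to the highest dose.
* Ki relations with inconsistent shifts (non-positive denominators): a
  classed error naming the relation; in batch profiling the affected dose
  is dropped from pooling.

# Known limitations

* The mechanism screen's false-change rate depends on the shared
  uninhibited baseline fit; an anomalous baseline shifts all per-dose
  comparisons together, which majority voting cannot fully undo.
* The competitive Ki relation's $K_i + I$ offset (see above) is inherited
  by the mixed-mechanism average at doses comparable to $K_i$.
* IC50 dialects are straight-line interpolators; their accuracy degrades
  on grids that are sparse or asymmetric about the midpoint.
* No global multi-dose inhibition fit is provided; per-dose fits are
  pooled instead, matching the per-concentration analysis the relations
  are defined for. A global fit is a documented extension point, not a
  default.
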