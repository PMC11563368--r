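---
title: "Auditing musculoskeletal models with muscle-tendon strain injury criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing musculoskeletal models with muscle-tendon strain injury criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtuaudit)
```

## The audit idea

A Hill-type muscle-tendon unit (MTU) outputs two quantities in essentially
every musculoskeletal simulation: the MTU force and the tendon strain.
During physiological movement neither should ever reach injurious levels in
a correctly built and correctly parameterised model. `mtuaudit` turns this
stipulation into a model-verification method: grade every muscle's trace
against strain-injury criteria and treat any crossing as evidence of a
modelling error — an unphysiologically deforming skeleton upstream of the
muscle, or an ill-tuned parameter set inside it.

Two criteria are implemented. The **MSIC** is force-based: its minor and
major thresholds scale with the muscle's maximum isometric force
$F_{max}$ and the momentary activity $a$, and rupture occurs at the force
to failure $F_{tf} = 3F_{max}$. This inherent scaling means the criterion
can never be mismatched to the muscle it grades. The **TSIC** is
strain-based, and a single fixed set of strain thresholds *can* be
mismatched: tendons occupy a wide compliance spectrum, from stiff
positional tendons (foot flexors, Young's modulus around 2.4 GPa) that
transmit force almost losslessly, to compliant energy-storage tendons
(Achilles, 0.5–0.8 GPa) that stretch past 10% strain in normal locomotion.
The package therefore derives a *tendon-specific* minor TSIC threshold for
any tendon with a linearisable force–strain curve.

Only the minor grade is used for the verdict. The Hill-type tendon curves
reproduce a nonlinear toe region and an infinitely continued linear elastic
region; at the large strains where plastic deformation, necking and rupture
occur the material models have lost validity. Major and rupture MSIC events
are still computed but flagged `beyond_validated`.

## The threshold construction

Everything happens in the normalised plane of tendon strain $\varepsilon$
(in percent) versus normalised force $F/F_{max}$.

**Boundary yield points.** Two archetype tendons anchor the construction.
The energy-storage boundary is an Achilles-like analytic stress–strain law
$\sigma(\varepsilon) = C\,\varepsilon\,e^{D\varepsilon + F\varepsilon^2}$
(defaults $C = 1.386$ MPa, $D = 0.123$, $F = -0.004$, strain in percent;
`energy_storage_stress()`). Converting the stress at its yield strain of
14.5% to force with a cross-sectional area of 77.50 mm² and normalising by
the 4172.97 N maximum isometric force of the attached plantar flexors gives
the yield point $(14.5, 0.96)$. The positional boundary, from foot-flexor
tensile tests, is represented directly by its yield point $(2.9, 1.92)$ and
its fitted line (slope 1.12/%, intercept −1.29): the underlying tabulated
data are not bundled, but `tabulated_curve()` accepts any 2-column
stress–strain table should a user wish to rebuild the corridor from their
own measurements.

**The yield line.** `interpolate_threshold_line()` joins the two boundary
yield points exactly:
$m_{int} = (y_{ens}-y_{pos})/(x_{ens}-x_{pos})$,
$c_{int} = (x_{ens}y_{pos}-x_{pos}y_{ens})/(x_{ens}-x_{pos}) = 2.16$. With
the default points the exact slope is $-0.96/11.6 = -0.0828$/%. The
*published* line carries a rounded slope of $-0.081$/%, and the published
family thresholds (4.77% and 8.67%) are consistent with the rounded value,
not the exact one; `reference_threshold_line()` therefore provides the
rounded line for reproducing the published table, while the interpolation
always returns the exact line. The residual between the two routes is under
1% of the threshold and traces to coefficient rounding.

**The intersection.** For a tendon whose linear region is
$y = m_{ten}\varepsilon + c_{ten}$, the minor threshold is the closed form
$x_{ten} = (c_{ten}-c_{int})/(m_{int}-m_{ten})$
(`derive_minor_threshold()`). Intersections outside the corridor
$[x_{pos}, x_{ens}]$ are returned *with a warning* rather than an error:
the boundary tendons themselves sit exactly on the corridor edges, and
tendons stiffer than the positional archetype are legitimate inputs whose
thresholds are mild extrapolations. Parallel lines raise an error. Far
outside the corridor the extrapolated normalised force can be non-positive;
the result object is built without the positivity check that user-supplied
yield points must pass.

## Tendon family curves and their calibration

The two Hill-type families are implemented with their native shapes:

* **TMM** (Thelen-type series-elastic element): exponential toe
  $F_{toe}\frac{e^{k_{toe}\varepsilon/\varepsilon_{toe}}-1}{e^{k_{toe}}-1}$
  up to $\varepsilon_{toe} = 0.609\,\varepsilon_0$, then a linear region of
  stiffness $1.712/\varepsilon_0$ per unit strain, where $\varepsilon_0$ is
  the strain at one maximum isometric force ($F_{toe}=0.33$, $k_{toe}=3$).
* **EHTM** (extended-Hill-type series-elastic element): power-law toe
  $f_0 (u/u_{nll})^{u_{nll}/\Delta U_l}$ up to the nonlinear–linear
  transition strain $u_{nll}$, then a linear region of normalised stiffness
  $f_0/\Delta U_l$. The exponent makes the junction C1-continuous.

The native shape parameters behind the published linearisations are not
public, so the package ships family defaults *calibrated to the published
linear regions*: for the TMM, $\varepsilon_0 = 1.712/52 \approx 0.0329$
makes the fitted slope exactly 0.52/% (the extrapolated intercept,
$0.33 - 1.712\cdot 0.609 = -0.713$, is independent of $\varepsilon_0$ and
matches the published −0.71 up to its rounding); for the EHTM,
$u_{nll} = 0.0425$, $\Delta U_l = 0.0175$, $f_0 = 0.42$ give slope 0.24/%
and intercept −0.60 exactly, and sit close to this family's customary
defaults. `calibrate_tendon()` exposes the same calibration as a 1-D root
solve on the stiffness parameter for any target slope. The calibration
reproduces the linear regions by construction; the toe regions are the
families' native shapes and may differ from any particular implementation's
tuning.

**Linearisation.** `fit_linear_region()` uses ordinary least squares over
$[\varepsilon_{toe} + 0.5\%,\ \varepsilon_{toe} + 5.5\%]$ (200 samples).
On the analytic curves this interval lies entirely in the linear branch, so
the fit is exact to machine precision; the margin of 0.5% strain guards
against junction effects on near-linear numerical curves. Raw point input
is fitted as supplied (optionally restricted by an `interval`), and fewer
than two points is an error, not a guess.

## MSIC configuration

Only two facts about MSIC thresholds are hard-coded: they scale with
$F_{max}$ and $a$, and rupture is $3F_{max}$. The published minor/major
coefficient values belong to the original MSIC publication and are *not*
bundled; `msic_thresholds()` takes arbitrary functions of $(F_{max}, a)$ or
coefficient pairs for the linear template $F_{max}(c_0 + c_1 a)$. The
shipped example config uses placeholder coefficients (minor $c_0=1$,
major $c_0=2.5$, both $c_1=0$) chosen only to order sensibly below the
rupture factor; they must be replaced with the published values before
auditing a real model. Threshold ordering (minor ≤ major ≤ rupture for all
$a \in [0,1]$) is validated at assessment time. A missing activity series
is treated as $a \equiv 1$ with a warning — for the usual positive scaling
this is the conservative choice.

## Crossing detection and grading

`detect_first_crossing()` reports the earliest time at which a series
reaches its threshold, linearly interpolated between the bracketing
samples; a sample exactly at the threshold counts as crossed, and a series
that starts above the threshold crosses at the first sample. Time-varying
MSIC thresholds (through $a(t)$) are handled by detecting the first
zero-upcrossing of the force margin. TSIC grading reports at most one minor
event per trace with the trace's peak strain attached; MSIC reports the
first crossing of each grade. `audit_model()` runs both criteria over a
set of traces and passes if and only if the event list is empty, with
events ordered deterministically by (muscle, time).

## The synthetic scenarios

The generator does not attempt to reproduce any specific gait model or its
muscle controller — those live in external model files. It reproduces the
*structural situation* the audit must detect, via quasi-static series
equilibrium: at each sample the tendon strain $\varepsilon$ solves
$F_{belly}(l_{MTU} - l_{SEE,0}(1+\varepsilon/100)) =
F_{max}F_t(\varepsilon)$, by bisection until the force residual is below
$10^{-8}F_{max}$ (expansion of the bracket, then at most 200 halvings; a
non-bracketable balance raises a diagnostic error; a residual already below
tolerance at zero strain means the MTU is slack and the strain is 0).

The muscle belly is deliberately minimal — a Gaussian active force–length
curve of width 0.45 and an exponential passive curve
$e^{k(\lambda-1)}-1$ active beyond the optimum length — the simplest forms
under which the equilibrium is well-posed against a monotone tendon. No
force–velocity relation, no activation dynamics, no pennation: the
scenarios are quasi-static by construction.

The default muscle is plantar-flexor-like ($F_{max}$ = 1558 N,
$l_{CE,opt}$ = 0.10 m, $l_{SEE,0}$ = 0.361 m, TMM tendon), and the
`gait_like` scenario runs one raised-cosine MTU-lengthening cycle
(amplitude 6 mm) with a synchronous activation bump (0.05 → 0.4) over
0.25 s at 400 Hz, starting at t = 0.83 s — the stance-to-swing window of a
partial gait cycle, 101 samples per trace. The passive stiffness $k = 1.7$
and the amplitude were fixed once so that the two bundled conditions
bracket the audit's decision boundary in the physiologically meaningful
way: with default parameters the tendon peaks at 2.1% strain and 0.40
$F_{max}$ (no event of any kind), while a 20% slack-length reduction
(0.361 m → 0.2888 m) pre-strains the tendon to 4.7% at the first sample —
still below the TMM minor threshold — and the cycle's MTU lengthening
carries it across mid-cycle, peaking at 5.19% and 1.98 $F_{max}$. The
failure signature is thus minor-grade-only, in both criteria, in exactly
the modified muscle. The `overstretch_ramp` scenario instead ramps the MTU
length at constant low activation, emulating the progressive over-stretch
of a muscle spanning a joint that is being pulled apart.

Randomness enters only as optional additive Gaussian strain noise under a
single integer seed; profiles are smooth and deterministic, so zero-noise
traces contain no spurious crossings.

What the scenarios do *not* emulate: inverse kinematics or any controller,
contact, inertia and damping transients, pennation geometry, or the
specific parameter files of any published gait model. Passing the audit on
these fixtures demonstrates that the grading logic and threshold derivation
behave correctly on traces with the right structure (pre-strain, cyclic
loading, monotone over-stretch); it is not evidence about any particular
external model.

## Numerical and interface choices

* Strain is in **percent** at every public interface and on disk; the
  analytic constants $D$ and $F$ carry per-% and per-%² semantics.
* Bisection tolerance $10^{-8}F_{max}$ on the force residual (not on the
  strain), matching what "equilibrium" means mechanically.
* OLS linearisation interval as above; exact on analytic linear branches.
* Degenerate inputs fail loudly: equal boundary abscissae, parallel
  intersections, non-positive slack lengths or thresholds, decreasing time
  stamps (with the offending row named), malformed storage files (with the
  line number named), unknown config keys (with the allowed set named).
* Trace files: CSV or OpenSim-style storage text; the storage dialect is
  accepted with or without `nRows`/`nColumns` header lines, which are
  validated when present. Column names match case-insensitively with an
  optional explicit mapping.
* Reports are schema-versioned JSON, byte-stable for identical inputs.
* CLI exit codes: 0 audit passed, 1 injuries detected, 2 usage/parse error.

## Known limitations

The criteria bound forces and strains from above only. A model whose
muscles remain slack through the whole range of motion produces no force,
no strain, and no injury — and no movement either; the audit would pass it.
The method is one instrument in a larger verification toolbox, not a
holistic assessment. The boundary corridor itself inherits the
uncertainties of the tendon literature (cross-sectional areas and maximum
forces from different sources, yield points not congruent across
experiments — the energy-storage boundary yields at just 0.96 $F_{max}$,
i.e. a maximal isometric contraction alone would nominally injure it);
when better data exist, redefining the corridor is a two-argument call.
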