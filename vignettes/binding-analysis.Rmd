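---
title: "Models and methods: bivalent-analyte SPR kinetics and companion assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: bivalent-analyte SPR kinetics and companion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindkin)
library(dplyr)
```

`bindkin` exists to answer a deceptively simple question — how strongly does
a dimeric receptor reagent bind its surface-immobilized ligand? — in the
common situation where the analyte's bivalency contaminates the measured
kinetics with avidity. This vignette is the package's account of its models,
its numerical choices, and what its validation does and does not show.

## The binding models

### 1:1 Langmuir

For analyte concentration $C$ flowing over a surface with capacity
$R_{max}$ (response units, RU), the bound response obeys
$dR/dt = k_{on} C (R_{max} - R) - k_{off} R$, giving the closed forms used
by `simulate_one_to_one()`:

* association: $R(t) = R_{eq}\,(1 - e^{-(k_{on}C + k_{off})t})$ with
  $R_{eq} = R_{max}\,C/(C + K_D)$, $K_D = k_{off}/k_{on}$;
* dissociation: exponential decay at rate $k_{off}$ from the
  end-of-injection bound level.

A bulk refractive-index jump `ri` is added only while analyte flows
(a rectangular pulse). Injection start defines $t = 0$; recorded baseline
samples carry negative times. We model no baseline drift in the analysis
path — drift exists only as an option of the synthetic generator, because
reference-subtracted instrument exports are normally flat.

### Bivalent analyte

A dimeric analyte first binds one ligand, then may bridge a second:

$$\frac{dAB}{dt} = k_{on1} C B_{free} - k_{off1} AB - k_{on2} AB\,B_{free} + k_{off2} AB_2,$$
$$\frac{dAB_2}{dt} = k_{on2} AB\,B_{free} - k_{off2} AB_2,$$

with $B_{free} = R_{max} - AB - AB_2$ and observed response
$AB + AB_2\,(+\,ri$ during association$)$. Two conventions in this scheme
are genuinely open and we fixed them deliberately:

* **Response bookkeeping.** The second binding event consumes a ligand site
  but adds no analyte mass, so $AB_2$ contributes one response unit, not
  two. This matches how evaluation software for these instruments treats
  bivalent analytes, and the simulator and fitter share the single scheme so
  parameter recovery is self-consistent.
* **Site stoichiometry.** Whether $AB_2$ should deplete one or two ligand
  equivalents from $B_{free}$ cannot be decided from published outputs of
  such fits. The default is one equivalent; `occupancy = 2` switches to the
  alternative bookkeeping in both the simulator and the fitter. It is a
  config switch, not a claim about ground truth.

Units deserve care: $k_{on2}$ is native to the surface and carries
RU⁻¹s⁻¹. For reporting, it converts to molar units as
$k_{on2}({\rm M^{-1}s^{-1}}) = k_{on2}({\rm RU^{-1}s^{-1}}) \times 100
\times MW$, with the analyte molecular weight in Da. The package never
assumes a molecular weight silently — `kinetic_constants()` refuses to run
without one. For the LAG-3:Fc reference parameter sets we adopt
$MW = 2\times10^5$ Da (an Fc-fused dimer of ~50 kDa ectodomains), a
documented default of `lag3_bivalent_params()`; note that the derived
$K_{D2} = k_{off2}/k_{on2}$ is independent of this choice because the same
factor enters the stored RU-unit rate and its back-conversion.

### Equilibrium of the bivalent scheme

At steady state the second-site fluxes balance, which collapses the
first-site balance to $AB = (k_{on1}C/k_{off1}) B_{free}$ and
$AB_2 = (k_{on2}/k_{off2}) AB\, B_{free}$. $B_{free}$ then solves a
quadratic, and `equilibrium_response_bivalent()` returns the admissible root
in closed form. The ODE integrated to long times reproduces this value to
well under 0.1 RU, which the test suite checks at several concentrations —
a genuine dual-route check, since the algebra never touches the integrator.

## Kinetic fitting

`fit_kinetics()` minimizes the sum of squared residuals over association and
dissociation samples (baseline excluded — instrument exports are typically
zeroed there, and including a structureless segment only dilutes the cost).
Choices that matter:

* **Positivity by construction.** All rate constants and $R_{max}$ are
  optimized as logarithms. The per-cycle `ri` offsets stay linear.
* **Global layout.** One surface means one $R_{max}$ and one set of rate
  constants shared across cycles; the refractive-index jump is per cycle
  (it varies with each injected sample). A published global fit reporting a
  single $R_{max}$ alongside a *range* of RI values is exactly this layout.
* **Optimizer.** Levenberg–Marquardt trust-region least squares
  (`minpack.lm::nls.lm`), cost tolerances $10^{-10}$, up to 100 iterations,
  with a deterministic five-point multi-start over rate-scale factors
  ($\times10^{\pm1}$ patterns). Deterministic starts — not random restarts —
  keep repeated fits bit-identical, which the tests assert.
* **Default guesses.** $k_{on1}=10^4$, $k_{off1}=0.1$,
  $k_{on2}=10^{-4}\,{\rm RU^{-1}s^{-1}}$, $k_{off2}=10^{-3}$,
  $R_{max} = 1.2\times$ the peak observed response, `ri` from the first
  association-sample jump over the trailing baseline mean.
* **Guard rails.** Parameter excursions beyond $e^{\pm45}$, integrator
  failures, or non-finite model output at a trial point return a flat
  penalty residual instead of crashing the line search; failing starts are
  dropped, and only if no start yields a solution does the fit error out
  (it never fabricates parameters).
* **Under-determination.** A fitted phase with fewer than 5 samples is
  refused.

### Goodness of fit

`gof_chisq()` implements $\chi^2 = \sum (obs - exp)^2 / exp$, the statistic
biosensor software prints next to such fits. Divided by an expected response
that passes through zero, it would explode, so the denominator is floored at
1 RU; the plain SSR is always reported alongside and `compare_models()`
ranks by $\chi^2$ with SSR and lag-1 residual autocorrelation shown, flagging
near-ties (improvement < 1%) as over-parameterization territory rather than
computing a formal test. The absolute $\chi^2$ of any real dataset depends
on its noise realization and sampling density; the package therefore treats
published $\chi^2$ magnitudes as descriptive, not as reproduction targets,
and validates fits by parameter recovery instead (a test asserts exactly
this data-dependence).

## Steady-state affinity

`extract_plateau()` reads the response at the sample nearest the requested
readout time (default 30 s into the injection; at ≤1 s sampling,
interpolation would change nothing) and subtracts the mean over the final
10 s of pre-injection baseline — the window is our choice, as published
captions state only the readout time. Steady state is not verified by
default because the low-density fast-kinetics regime reaches equilibrium in
seconds; `check_plateau = TRUE` warns when the trailing association slope
exceeds 1 RU/s. `fit_one_site()` fits $R = B_{max}C/(K_D + C)$ with both
parameters free (log-scale, unconstrained $B_{max}$ — we found no statement
that the original analysis constrained it) and flags designs whose
concentrations all sit far above the fitted $K_D$, where $K_D$ is
unidentifiable.

`analyze_density_series()` quantifies the avidity signature: apparent
dissociation half-time (first halving of the bound response after injection
stop, linearly interpolated) per immobilization density. Under the bivalent
scheme, half-time grows with $R_{max}$; under 1:1 kinetics it is
density-independent. Both directions are property-tested.

## Plate assays

Cross-titration summaries subtract the mean buffer-alone background (floored
at zero, idempotent), then per acceptor concentration report the peak
fold-over-background and a Spearman rank trend of signal versus donor
concentration over the pre-hook region. The binding call — positive at peak
fold ≥ 3 and trend ≥ 0.8 — formalizes what is usually an by-eye judgement;
the thresholds are package-defined and exposed as arguments. The hook
effect (post-peak signal collapse when excess free analyte saturates the
beads separately) is flagged at a ≥ 20% drop from the maximum.

`fit_inhibition()` fits the four-parameter logistic
$S = bottom + (top - bottom)/(1 + (c/IC_{50})^h)$ with the Hill slope free
(published blockade results state an IC50 but not a fixed-slope model), IC50
on the log scale, and counts treated as continuous with additive noise —
these are amplified arbitrary-unit counts, not Poisson events.

## Flow quantification

Geometric MFI over live events only; FMO subtraction floored at zero with a
flag; percent-positive gating at the 99.9th percentile of the reference
sample (FMO or irrelevant-multimer control — the published gates are visual,
so a rank-based rule was chosen for its invariance under monotone intensity
transforms, which is also property-tested); blockade normalization
$100 (cond - fmo)/(ctrl - fmo)$. Event tables arrive as plain intensity/live
columns: cytometry file parsing, compensation and transformation live
upstream, keeping the module instrument-agnostic.

## Synthetic data: what it emulates, what it does not

The generators reproduce the *designs* of the experiments this analysis
chain serves:

* `gen_sensorgrams()`: twofold dilution series (defaults spanning
  0.11–57 µM), 30 s association / 300 s dissociation at 1 s sampling, i.i.d.
  Gaussian noise of sd 2 RU (instrument-typical short noise; the original
  reports none) and optional linear drift.
* `gen_titration_plate()`: one-in-three donor series 0.3–300 nM against
  three acceptor concentrations, 5% CV multiplicative noise, optional hook.
  The absolute count scale of bead-proximity readers is never published, so
  the background level (1000 counts) and 30-fold peak signal are arbitrary
  and clearly labelled as such.
* `gen_inhibition_series()`: one-in-three series over ~5 decades around a
  default IC50 of 1.32 nM, Hill 1, 5% CV.
* `gen_flow_events()`: log-normal autofluorescence (log-sd 0.5) with a
  shifted positive population at a configurable fraction and a 5% dead-event
  rate.

They deliberately do **not** emulate: reference-cell subtraction artifacts,
injection carryover, mass-transport limitation, temperature effects (all
analyses assume the original 25 °C without modelling it), bead-coating
stoichiometry, or full cytometry gating trees. Passing recovery tests
therefore demonstrates that the estimators are correct and well-conditioned
under the stated noise models — not that they are robust to every artifact
of real instrument data.

## Numerical conventions

* Integration: lsoda (stiff-capable) with rtol $10^{-8}$, atol $10^{-6}$ RU,
  compiled right-hand side; all concentrations of a series are stacked into
  one system per phase segment, which is why global fits of seven-cycle
  series take around a second.
* Concentrations are molar internally; plate and inhibition interfaces use
  nM, matching how those assays are designed.
* CSV interfaces write 17 significant digits and parse through
  correctly-rounded conversion, so sensorgram files round-trip bit-exactly.
* Validation problem sizes: 20-replicate recovery studies for the kinetic
  (seven concentrations, 331 samples each), steady-state (10-point isotherm)
  and IC50 (12-point series) designs; 100-replicate hook-detection
  concordance; these sizes give stable medians while keeping the full suite
  around a minute.

## Known limitations

* The bivalent fitter assumes one homogeneous ligand population and no
  mass-transport limitation; heterogeneous-ligand and two-state models are
  out of scope.
* Local (single-concentration) bivalent fits are weakly identifiable by
  nature; they are supported because the single-cycle layout is part of the
  standard reporting, but global fits should carry the interpretive weight.
* No uncertainty quantification beyond SSR/χ² is attempted (no bootstrap or
  Bayesian posterior); published instrument-software error estimates have no
  counterpart here.
* The steady-state route inherits the usual caveat that residual avidity at
  "low" density biases $K_D$ slightly strong; the package quantifies this by
  the kinetic/steady-state consistency ratio in `run_binding_analysis()`
  rather than attempting to correct it.
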