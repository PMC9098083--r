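---
title: "Escape-behavior models and their sensitivity to vehicle approach speed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Escape-behavior models and their sensitivity to vehicle approach speed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidsim)
library(dplyr)
```

## The problem

Animals confronting an approaching vehicle behave much as they do with an
approaching predator: they become alert at some distance (the alert
distance, AD) and initiate escape at a shorter one (the flight initiation
distance, FID). Antipredator theory offers several models that predict FID,
but all of them were developed for predator-scale speeds. Vehicles travel
an order of magnitude faster, and whether a model's predicted FID responds
to approach speed at all determines whether it is useful for managing
collision risk. `fidsim` implements the five escape-behavior models that
yield quantitative FID predictions, an effect-size simulation that asks how
sensitive three of them are to approach speed, and the Critical Vehicle
Approach Speed (CVAS) metric for management.

A single encounter is described by the distance ladder
`0 <= FID <= AD <= SD` (SD: starting distance at which the vehicle enters
sensory range) and, at constant approach speed `v`, the time to collision
`TTC = d / v`. All internal units are metres, metres per second, seconds
and kilojoules; km/h appears only at reporting boundaries (factor 3.6).

## The models

**Perceptual limits.** Escape happens at detection, and detection is set by
visual acuity: an object of width $w$ is resolvable once it subtends one
grating cycle, $\theta_{min} = 1/\text{acuity}$ degrees, i.e. out to
$d = (w/2)/\tan(\theta_{min}/2)$. For a 4.82 cycles-per-degree viewer and a
1.73 m car this gives `r round(perceptual_limit_fid(4.82, 1.73), 1)` m.
Published applications of this calculation quote ~474.7 m, about 0.6% below
the exact trigonometric value; the convention behind the published figure
is not stated, so the package uses the exact form and treats agreement
within 1% as equivalence.

**FEAR (flush early and avoid the rush).** Animals escape soon after
becoming alert to cut monitoring costs, so FID should track AD along the
1:1 origin line. The phi index measures that tracking as the
per-observation standardized proximity $\Phi = \mathrm{mean}(FID_i/AD_i)$,
which is 1 when every escape coincides with alert, 0 when no animal
escapes, and 0.5 under the uniform null ($FID \sim U(0, AD)$). Significance
comes from simulating null phi values at the observed ADs
(`phi_significance()`); support for the hypothesis requires $\Phi > 0.5$
and $p < 0.05$. Predicted FID multiplies the through-origin regression
slope by the 5th percentile of AD (empirical quantile with linear
interpolation, the conventional definition).

**Looming stimulus.** Escape is triggered when the optical variable
$\tau = \theta/\theta'$ (visual angle over its expansion rate, an optical
proxy for time-to-collision) falls to a neural threshold, followed by a
neuronal latency $\delta$ during which the vehicle keeps closing:
$FID = d_\tau - \delta v$, floored at 0. For a circular profile of radius
$r$, $\tau(d) = \arctan(r/d)\,(d^2+r^2)/(rv)$; `looming_base_from_tau()`
inverts this on the approaching branch. Because the visual angle saturates
as the object fills the visual field, $\tau$ cannot fall below about
$\pi r/(2v)$; thresholds under that bound resolve to escape at contact
(distance 0). The latency can be estimated from behavioral data as the
intercept of mean escape TTC regressed on the size/speed ratio
(`estimate_neuronal_latency()`).

**Visual cue.** Escape is triggered when the change in the
profile-size-to-distance ratio $A(d) = \kappa w / d$ between a first
(far) and a closer viewing distance exceeds a threshold $\Delta A$.
Habitat complexity (vegetation in $[0,1]$) attenuates the perceived change
and an individual-difference term shifts it; the predicted FID is the root
of $g(d) = \Delta A_{thr} - [(1-veg)(\kappa w/d - \kappa w/d_1) + ind]$,
found by bisection to $10^{-6}$ m. With no vegetation or individual term
the root has the closed form $\kappa w / (\Delta A_{thr} + \kappa w/d_1)$,
which the tests use as an oracle.

**Bayesian optimal escape.** The animal flees at the first distance where
the one-off energetic cost of fleeing stops exceeding the perceived cost of
remaining, i.e. its daily energy budget weighted by the perceived
probability of attack. The energetics are allometric: flight power
$W = 61.72\,M_b^{0.79}$ (mass in kg), escape cost $W \times$ escape time
(J converted to kJ), and daily energy expenditure
$DEE = -0.80 + 0.66\,M$ (mass in **grams** — the two allometries were
fitted on different mass scales and the package keeps each one's original
units). The cited source for the risk functions is not reproduced in the
available text, so the package supplies its own operationalization of the
verbal description, exposed as a pluggable `bayes_risk()` object: a
proportional-distance cue $x_1 = 1 - d/AD$ and a speed-ratio cue
$x_2 = \min(v/v_{esc}, 1)$ combined by Bayes' theorem with the behavioral
prior $\alpha$ (0.5 = no bias). Maximum escape speed scales as $M^{1/6}$
(standard avian flight-speed allometry) anchored at the observed cowbird
value, 3.75 m/s at 43.9 g. The decision is scanned on a 0.01 m descending
grid from AD (`bayesian_fid()`), ties resolving to the larger distance;
tests check the scan against a 10× finer one.

**CVAS.** For a species that keeps a constant (spatial-margin) FID across
vehicle speeds, `cvas(fid, t) = (fid / t)` expressed in km/h is the vehicle
speed above which the animal cannot clear the path in its escape time even
with perfect detection: 28 m and 0.80 s give
`r round(cvas(28, 0.80))` km/h.

## The simulation

The speed-sensitivity analysis generates encounters on a grid crossing
approach speeds 1–100 m/s (1 m/s steps; human walking pace up to aircraft
take-off speed) with FID-vs-speed slopes −37…32 (unit steps, spanning the
range estimated across 50 bird species). Per cell, AD is drawn from
Normal(48.55, 10.51) m — detection is assumed speed-invariant, and
non-positive draws are redrawn — and FID from
Normal(slope × speed + 42.98, 31.08) m, censored to [0, AD]: escape can
happen neither before detection nor after contact. One iteration yields
7,000 AD/FID pairs and the default 100 iterations 700,000. All defaults sit
in `sensitivity_config()`; a single sequential RNG stream per run (rather
than per-iteration substreams) makes any seed byte-reproducible.

Effect sizes are computed per (slope, iteration) cell first and then
averaged over iterations: the phi index (FEAR) or, for the looming and
Bayesian models, an ordinary regression of model-predicted FID on speed
converted to Cohen's $f^2 = R^2/(1-R^2)$ (anchors 0.02/0.15/0.35 for
small/medium/large, left-closed intervals). Slope regions map to escape
rules: negative slopes (delayed margin of safety — escape delayed more at
higher speed), zero (spatial margin — fixed escape distance), positive
(temporal margin — fixed escape time). The looming model adds a latency
grid (25 even values over 0.05–0.1 s, the measured pigeon range; 0.075 s is
the 2-D summary) and the Bayesian model a body-mass grid (50 log-even
values, 11.5 g–6.22 kg; the geometric mean 267.4 g is the 2-D summary).

The *slope window* analysis asks which slopes are operationally
indistinguishable from zero in an experiment: 8 speed treatments
(60–360 km/h), 20 FID points each, AD ~ Normal(50, 10), intercept 25 m
(half the mean AD), FID SD 10 m, 500 iterations; per cell an F-test of FID
on treatment as a categorical factor, per slope the mean p, and the window
is the contiguous run of slopes around 0 with mean p above α = 0.05. On
the 0.05-step grid this lands at [−0.1, 0.1]. Slopes far outside the
censoring band (|slope| ≳ 2 here) pin FID to AD or 0 and lose the speed
signal entirely — their mean p returns to ~0.5, which is why the window is
defined by contiguity around zero rather than by thresholding alone.

## What the generator does and does not emulate

The generator reproduces the *distributional design* of the sensitivity
analysis — speed-invariant normal AD, linear-in-speed FID with normal
noise, hard censoring to [0, AD] — not real field data: no species
structure, no AD–FID correlation beyond censoring, no repeated measures of
individuals, no habitat covariates. Passing tests therefore show that the
models and statistics behave as designed under these study conditions, not
that any real species follows a given escape rule. The packaged 50-row
species table (`load_species_fixture()`) is likewise synthetic: it matches
the published review's column summaries (means, SDs, ranges; body masses
log-even from 11.5 g to 6.22 kg) without reproducing any real species' row.

## Numerical choices

Bisection tolerance 1e-6 m (visual cue); tau inversion by `uniroot` on the
approaching branch to 1e-9; Bayesian scan step 0.01 m from AD downward,
first hit wins; regression effect sizes via closed-form simple regression
on the shared speed grid, with degenerate (zero-variance) cells set to
$f^2 = 0$ with a warning; censoring sets values to the violated bound
(rather than rejection sampling), matching the stated simulation rules; AD
draws at or below 0 (probability ~2e-6 per draw) are redrawn. Cohen class
boundaries are left-closed. The empirical 5th percentile uses R's default
type-7 interpolation.

## Problem sizes

Full scale (100 iterations; as in `scripts/acceptance.R` for the FEAR and
looming analyses) runs in roughly a minute on one core. The packaged tests
use 20-iteration runs for the FEAR/looming checks (tolerances widened
accordingly) and 5 iterations for the Bayesian check, whose 0.01 m
per-sample scan dominates its cost; the slope-window analysis always runs
its full 500-iteration design. The Bayesian region means are chance-level
quantities (see below), so their estimates stabilize at far fewer
iterations than the phi surfaces.

## Known limitations

- The Bayesian model's published behavior at large body mass — speed
  sensitivity rising to a medium effect near 6.22 kg — is *not* reproduced
  by this implementation, and the corresponding check is deliberately left
  failing. Under the flee rule as printed (escape cost vs. DEE-weighted
  attack probability), the threshold probability cost/DEE is of order
  1e-4 across the entire 11.5 g–6.22 kg range, because the daily energy
  budget always dwarfs a single escape flight's cost. Any risk weighting
  bounded in [0, 1] then places the predicted FID within a fraction of a
  metre of AD at every mass and speed, so predictions are speed-flat and
  the regression $f^2$ sits at the chance level of an n = 100 regression
  (~0.0105) — which is precisely the published small-mass region value
  (0.009–0.011), but cannot produce the published large-mass rise.
- The perceptual-limit worked value and the printed escape cost
  (7.83e-3 kJ vs. the 4.18e-3 kJ implied by the printed equations) carry
  small unexplained discrepancies, documented above; the package implements
  the stated equations.
- Predictions that require the original cowbird trial data (per-treatment
  AD/FID/TTC summaries) are supported as workflows — the functions accept
  user-supplied summary tables — but their published numeric outcomes are
  not asserted anywhere, since the inputs are not public.

## A worked run

```{r example, fig.width = 6, fig.height = 3.5}
cfg <- sensitivity_config(n_iterations = 5, seed = 42)
grid <- simulate_sensitivity_grid(cfg)
fear <- fear_sensitivity(grid, n_phi_sim = 100)
summarize_regions(fear)
autoplot(fear)
```

```{r window, fig.width = 6, fig.height = 3.5}
win <- slope_window(simulate_slope_window_data(
  slope_window_config(n_iterations = 100, seed = 42)))
win
classify_escape_rule(c(-3, 0.05, 12), win)
autoplot(win)
```
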