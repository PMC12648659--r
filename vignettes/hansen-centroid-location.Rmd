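---
title: "Locating materials in Hansen space from absorbance panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating materials in Hansen space from absorbance panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsploc)
```

## The problem

Hansen solubility theory places every substance at a point
$(\delta_D, \delta_P, \delta_H)$ in a three-dimensional space of cohesive-energy
contributions — dispersion, dipolar and hydrogen bonding, each in
MPa$^{1/2}$ — and quantifies solvent–solute compatibility by the Hansen
distance

$$R = \sqrt{4(\delta_D^{(1)}-\delta_D^{(2)})^2 +
            (\delta_P^{(1)}-\delta_P^{(2)})^2 +
            (\delta_H^{(1)}-\delta_H^{(2)})^2},$$

with the conventional factor of 4 on the dispersion axis. For ordinary
molecules the three parameters can be computed from group contributions or
looked up. For amorphous porous organic polymers (POPs) — polydisperse,
cross-linked, of essentially unknown molecular structure — no bottom-up route
exists, and sphere-fitting approaches require classifying solubility into a
binary good/poor score, which is both slow and lossy for materials that never
truly dissolve.

`hsploc` implements an alternative: suspend the material in a small panel of
solvents that spread across Hansen space, read the UV/vis maximum absorbance
of each suspension (consistently from the same absorption band), and treat
each absorbance as a *solubility score*. Two working hypotheses connect score
to geometry: a better solvent (1) lies closer to the material in Hansen space
and (2) suspends more material, giving a stronger absorbance. The material's
location is then a one-cluster centroid problem.

## The estimator

Given solvents $\delta_{S_i}$ with weights $w_i$ (the raw absorbances), the
estimate $\delta_M$ minimizes the total weighted Hansen distance

$$\hat\delta_M = \arg\min_{\delta_M} \sum_{i=1}^n w_i\, R_i(\delta_M).$$

After rescaling the dispersion axis by 2 this is the classical weighted
geometric-median (Fermat–Weber) objective: convex, with a unique minimizer
whenever the solvents are not collinear. Two properties follow directly and
are exercised by the test suite:

* **Scale invariance** — multiplying all weights by $c > 0$ leaves the argmin
  unchanged, which is why the weights are raw absorbances with no
  normalization, blank subtraction or calibration.
* **Majority weight** — if one solvent carries more weight than all others
  combined, it is itself the minimizer. A panel dominated by one excellent
  solvent simply returns that solvent.

### Initialization

Minimizing the *squared* form $\sum_i w_i^2 R_i^2$ instead gives a closed
form, because squaring removes $R_i$ from the gradient denominator:

$$\delta_M^{init} = \frac{\sum_i w_i^2\, \delta_{S_i}}{\sum_i w_i^2}.$$

The squared weights preserve the ordering of the original weights, and the
result is a convex combination of the panel solvents, so the search starts
inside the physically meaningful region — the component-wise box of the
panel — rather than at an arbitrary point.

### Descent and stopping

From that initializer, fixed-step gradient descent applies

$$\Delta = -\alpha \frac{d}{d\delta_M}\sum_i w_i R_i(\delta_M), \qquad
  \delta_M \leftarrow \max(\delta_M + \Delta, 0),$$

with learning rate $\alpha = 0.01$, stopping when $\lVert\Delta\rVert_2$
falls below the threshold `tol` $= 0.005$ MPa$^{1/2}$ or after 10,000 steps.
Clamping to the non-negative orthant is the minimal projection keeping every
iterate a candidate for a real solvent environment. There is deliberately no
line search or momentum: the step rule *is* part of the method's contract
(see below).

Where an iterate coincides with a solvent (distance below `eps_guard`,
default $10^{-9}$), that solvent's gradient term is dropped — a valid
subgradient at the kink that avoids division blow-up and makes a
majority-weight solvent a (one-step) attractor.

### The stopping rule is part of the estimate

A point worth stating plainly, because it shapes everything the validation
modules report: with a fixed step, the rule
$\lVert\Delta\rVert < \mathrm{tol}$ is equivalent to
$\lVert\nabla f\rVert < \mathrm{tol}/\alpha$ (0.5 with the defaults). The
returned estimate is therefore the *first iterate inside that gradient
shell*, not the exact minimizer. On the bundled case-study panel the
difference is visible: the exact weighted median coincides with the
best solvent of the panel (THF, a vertex of the objective), while the
reported estimate stops a little under $0.1$ MPa$^{1/2}$ short of it — and it
is the stopped iterate, rounded to two decimals, that reproduces the
published reference values. Consequences:

* Different random starts stop at different points of the shell. The
  multistart report (`multistart_validate()`) therefore measures the shell
  width — about $0.3$ MPa$^{1/2}$ on the case panel — and not estimator
  multimodality; the objective is convex and has one minimum.
* No choice of `tol` makes the shell arbitrarily tight relative to `tol`
  itself: agreement of all starts within $2\,\mathrm{tol}$ would need local
  curvature at least $1/\alpha$, while step stability bounds curvature by
  $2/\alpha$ on every axis, and the factor-4 dispersion anisotropy pushes the
  $\delta_D$ curvature several-fold above the transverse one. The
  `agree` flag of the multistart report implements the $2\,\mathrm{tol}$
  comparison as documented, and on realistic panels reports disagreement —
  by design, that is information about the stopping rule, not a failure of
  the optimization.
* For accuracy-critical comparisons (the grid-oracle tests), the suite runs
  the same algorithm with a smaller step and threshold
  ($\alpha = 10^{-3}$, tol $= 10^{-6}$), which shrinks both the shell and
  the near-vertex chatter to a few $10^{-3}$ MPa$^{1/2}$.

## Validation oracles

`grid_oracle()` minimizes the same objective by brute force on a regular
grid (chunked by dispersion slice; a configurable cell cap guards memory),
breaking ties lexicographically. It is independent of the descent code path
and anchors the correctness tests. One resolution caveat, observed on a
randomized panel and kept in the tests as a documented disjunction: when the
minimum sits *on* a solvent and one outgoing direction of the surrounding
cone is much shallower than the rest, the best 0.05-step grid point can
wander a couple of steps along that trough while the descent iterate sits at
the true vertex with a *lower* objective. The tests therefore accept either
positional agreement within one grid step or outright objective dominance of
the iterate over the best grid point.

`multistart_validate()` re-runs the locator from seeded uniform starts in a
bounding box (default $[14,20]\times[0,19]\times[0,43]$, spanning the
practical solvent region) and reports per-start outcomes and the dispersion
of converged estimates.

## Synthetic panels

`simulate_absorbance()` generates panels with exactly the structure the
estimator assumes:

$$\mathrm{abs}_i = \max(\mathrm{floor},\;
  A\, e^{-R_i/\tau} + \varepsilon_i), \qquad
  \varepsilon_i \sim \mathcal N(0, \sigma^2),$$

the simplest monotone-decreasing response consistent with the two working
hypotheses; no quantitative absorbance–distance law is claimed by the theory,
so the model is explicit and injectable. Defaults: amplitude $A = 0.8$ AU
(well-matched solvents in real panels top out near 0.7), decay scale
$\tau = 5$ MPa$^{1/2}$ (absorbance falls to $1/e$ across the spread of a
well-chosen panel), noise $\sigma = 0.02$ AU (routine UV/vis repeatability),
floor $0.01$ AU (baseline). The floor also truncates the Gaussian noise at
zero, since absorbance is non-negative.

What the generator does *not* emulate — and what recovery tests therefore
cannot certify about real data: Beer–Lambert concentration and path-length
effects, band shapes and band overlap (the benzenoid/quinoid ambiguity that
makes consistent band selection a user responsibility), scattering artifacts
of suspensions, and any systematic chemistry linking absorbance to specific
interactions. Recovery experiments (`recovery_experiment()`) quantify the
estimator under its own assumptions: near-exact recovery when a dominant
anchor solvent sits at the truth, and the inherent pull of the estimate into
the panel's convex hull (in scaled space) when no solvent is near the truth —
the estimator interpolates, it does not extrapolate.

## Numerical choices

* Display rounding is two decimals, half-up, matching the reference tables;
  full precision is kept internally and in exported ranking CSVs (17
  significant digits, so files round-trip exactly).
* The reported "global error" is the convergence threshold rounded half-up
  to the display decimals ($0.005 \to 0.01$); it is stopping-rule metadata,
  not a statistical uncertainty.
* Measurements are re-ordered internally by byte-wise solvent name before
  any floating-point reduction, so the estimate is bit-for-bit independent
  of input row order.
* Ranking ties (equidistant solvents) break alphabetically; grid-oracle ties
  break lexicographically in $(\delta_D, \delta_P, \delta_H)$.
* Database lookups are case-insensitive over names and synonyms, exact over
  CAS numbers; CAS check-digit mismatches warn rather than fail.

## Problem sizes

The shipped tests run the full case-study panel (14 solvents), randomized
property checks on panels of 3–8 solvents, grid oracles at $0.05$ step over
panel-sized boxes ($\sim 10^6$ cells), multistart validation with up to 20
starts, and recovery experiments of 4–6 trials — sizes chosen so the whole
suite exercises every code path in well under a minute on one core while
the accuracy-critical comparisons still run the descent to $10^{-6}$
thresholds.

## Known limitations

* The estimate inherits the stopping-rule offset described above; users who
  want the exact weighted median can tighten `alpha`/`tol`, at the cost of
  the vertex-chatter behavior near panel solvents.
* Panel geometry matters: collinear or tightly clustered panels give flat,
  ill-conditioned objectives. The bundled default panel spans
  $\delta_D$ 14–19, $\delta_P$ 0–18, $\delta_H$ 0–42 MPa$^{1/2}$ for this
  reason.
* Absorbances must come from the same band of the same aliquot protocol;
  the package documents but cannot enforce this.
* Out of scope by design: Hansen-sphere radius fitting, relative energy
  difference (RED) scores, temperature dependence of parameters, solvent
  blends, and any interpretation of gas-uptake or yield data.
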