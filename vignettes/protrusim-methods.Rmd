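---
title: "The protrusim model: stochastic chemosensing, protrusion mechanics and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The protrusim model: stochastic chemosensing, protrusion mechanics and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protrusim)
```

protrusim simulates the slow, adhesion-dependent (mesenchymal) migration of a
single fibroblast embedded in a 3D collagen matrix, and calibrates the model
against quantified microscopy features with multi-objective Bayesian
optimization. This vignette is the package's own account of the model, its
numerical choices, and the open design decisions we resolved — including the
ones a user should understand before trusting any particular number.

## The three-stage model

A cell is a set of one-dimensional bars (dendritic protrusions) radiating
from a central body of radius $r$ (default 10 µm). Each mechanical step
(every $dt = 5$ min, matching the imaging cadence of the experiments the
model emulates) runs three stages:

**1. Chemosensing.** A four-reaction network couples the chemoattractant
(PDGF, concentration $[F]$, treated as external and non-depleted) to
receptor and kinase pools:

$$\mathrm{RTK} + F \underset{k_2}{\overset{k_1}{\rightleftharpoons}} \mathrm{RTKF},
\qquad
\mathrm{RTKF} + \mathrm{PI3K} \xrightarrow{k_3} \mathrm{RTKF} + \mathrm{PI3K_A},
\qquad
\mathrm{PI3K_A} \xrightarrow{k_4} \mathrm{PI3K}.$$

Counts start at 4275 receptors and $75\times10^3$ kinase molecules; rates are
the literature values $k_1 = 735\ \mathrm{nM^{-1}s^{-1}}$,
$k_2 = 0.01\ \mathrm{s^{-1}}$, $k_3 = 4\times10^{-4}\ \mathrm{s^{-1}}$ (applied
per RTKF–PI3K pair), $k_4 = 1\ \mathrm{s^{-1}}$. Both second-order constants
are applied literally as printed; their implied volume scaling is not stated
in the source literature, so both are exposed in the configuration for
alternative unit interpretations. Two conservation laws —
$X_{RTK}+X_{RTKF}$ and $X_{PI3K}+X_{PI3K_A}$ — hold exactly along every
trajectory and are asserted in the tests.

The network advances by tau-leaping: each leap fires Poisson counts
$k_j \sim \mathrm{Pois}(a_j\tau)$ with the bounded relative-change criterion
of Cao, Gillespie and Petzold (2006) at $\varepsilon = 0.03$ selecting the
candidate $\tau$, clamped into $[0.5, 1.5]$ s. A leap that would drive any
count negative is rejected and retried at $\tau/2$; below a floor of
$10^{-3}$ s the stepper falls back to exact SSA for that short interval. The
final leap of each 5-minute window is truncated so windows tile exactly.
Note one consequence of the literal rate constants: $k_1[F]$ is so large at
any realistic dose that free receptors rebind within microseconds, so the
receptor channel is permanently stiff and the clamped lower bound of 0.5 s
is what makes the scheme practical; the rejection/SSA fallback absorbs the
stiffness. An exact SSA stepper and the deterministic mass-action ODE system
(solved with deSolve) exist purely as cross-checking oracles, and the
compiled window stepper mirrors the reference R implementation call-for-call
on R's RNG, so the two backends are bit-identical under a seed.

**2. Surface signal and protrusion dynamics.** The membrane is a flattened
chart over $\alpha \in [0, 2\pi)$ (periodic) and $\beta \in [0, \pi]$.
Each window's $n_3$ activation events are allocated to sites with
probability proportional to the local chemoattractant concentration (the
inverse-CDF method for a non-homogeneous Poisson field), and the $n_4$
deactivation events are allocated uniformly: activation happens where
ligand-bound receptors sit, whereas spontaneous deactivation of the
cytosolic kinase carries no spatial bias. Both maps are smoothed with a
truncated Gaussian kernel ($\sigma = 2$ sites, radius $3\sigma$), circular
in $\alpha$ and reflective at the poles (implemented exactly by an even
extension followed by torus FFT convolution, which conserves mass to
$10^{-9}$ relative and is exactly linear and rotation-equivariant).

Two fields are maintained:

* $s$, the cumulative *persistence* signal: the running sum of smoothed
  activation deposits, monotone non-decreasing. It is compared against the
  binarization level $s_{binary}$ and the thresholds $s_{birth}, s_{exp},
  s_{ret}$.
* $\delta s$, the *net variation* accumulated since the last mechanical
  step: smoothed activations minus smoothed deactivations. At chemical
  steady state it is zero-mean with per-site standard deviation
  $\approx \sqrt{2u}\,\lVert g\rVert_2$ ($u$ the per-site deposits per
  window), which under the default configuration is a few tens — the same
  scale as the calibrated $\beta_{exp} = 100$ and $\beta_{ret} = 54.86$.
  This split is deliberate: retraction and protrusion death require a signal
  variation that can be negative, which a monotone sum of deposits cannot
  provide, while the calibrated $s_{binary} = 62500$ is exactly the scale of
  the *cumulative* deposit count. No single field can satisfy both roles.

Candidate protrusion centroids are local maxima of $s$ within the binarized
mask ($s \ge s_{binary}$), thinned to a minimum separation (default 5 sites
on the 36×18 grid). A candidate with $s > s_{birth}$ and $\delta s > 0$ and
no live protrusion within the separation births a new protrusion; a live
protrusion with $\delta s \ge 0$ reinforces when $s > s_{exp}$ (else holds);
with $\delta s < 0$ it retracts, or dies outright when $s < s_{ret}$ (no
death at equality). Connected-component centroid extraction (8-connectivity,
periodic in $\alpha$) is also provided and selectable as the birth mode; we
default to peaks because the binarization's purpose is to restrict the peak
search, and once the cumulative signal exceeds $s_{binary}$ everywhere the
single surviving component would otherwise throttle the cell to one
protrusion.

The free (unconstrained) length increment is the saturating law
$\Delta\ell^f = \alpha\,\delta s/(\beta + \delta s)$, bounded by $\alpha$
(0.14 mm calibrated for expansion, 0.05 mm for retraction with
$\delta s < 0$; when $\beta_{ret} + \delta s \le 0$ the retraction saturates
into full collapse and the protrusion dies). We read the typeset strain law
as this ratio: the product reading diverges with the calibrated constants,
while the ratio yields bounded, biologically sized increments. The free
strain $\varepsilon^f = \Delta\ell^f/\ell$, capped at $|\varepsilon| \le 1$
(infinitesimal-strain regime), is then constrained by the surrounding matrix
via Eshelby's ellipsoidal-inclusion solution,

$$\tilde\varepsilon^c = S\,[(C_I - C_M)S + C_M]^{-1} C_I\,\tilde\varepsilon^f,$$

with the protrusion modeled as a prolate spheroid (aspect ratio
$\max(\ell/d, 1)$, diameter $d = 2$ µm), $E_I = 10^7$ Pa calibrated,
$E_M = 10^4$ Pa for a 2 mg/ml collagen gel, $\nu_I = \nu_M = 0.3$. The
closed-form Eshelby components are verified in the tests against numerical
elliptic integrals, a dense first-principles 9×9 tensor evaluation, the
sphere closed form $(7-5\nu)/(15(1-\nu))$, and the rigid/soft-matrix limits.
Newborn protrusions point radially outward through their centroid and seed
at the Eshelby-constrained free increment, so birth and growth stand on the
same mechanical footing.

**3. Translocation.** Only the longest (leading) protrusion adheres; ties
break to the earliest birth. Its contractile traction
$F = \alpha_{adh}\,\lVert p_{lp}\rVert$ balances Stokes drag $6\pi r\eta v$,
giving a piecewise-constant velocity along the protrusion axis, integrated
by explicit Euler at $dt$ (higher order would add nothing to a piecewise
constant velocity). The motion constants are not printed in the source
material; the defaults $\eta = 7.5$ Pa·s and $\alpha_{adh} = 1$ pN/µm give
speeds below ~3 µm/min, the right order for mesenchymal migration, and are
configuration-exposed.

## Grid resolution: a derived default

The membrane resolution is never stated in the source material, but it is
not free either — the calibrated $s_{binary} = 62500$ pins it. The literal
kinetics deposit $\approx 1.42\times10^7$ activation events per 5-minute
window; protrusions must exist from the earliest checkpoints (otherwise the
published length statistics would require a negative live-pool variance), so
the per-site cumulative signal must reach $s_{binary}$ within the first few
windows. That bounds the grid to roughly 230–650 sites. We use 36×18 = 648
sites, which crosses at window ~3 and whose peak-packing limit at the
default separation (9–12 concurrent protrusions) matches the published
concurrent-count range. The finer 72×36 grid remains available in the
configuration, but with the literal kinetics it delays binarization to
$t \approx 60$ min and suppresses the protrusion count — a documented
internal inconsistency of the published parameter set rather than a tunable
preference.

## Calibration

Each evaluated parametrization runs a fixed shared seed set (20 seeds in
production, fewer in the scaled studies), pools each run's checkpoints into
normalized histograms — 20-µm bins over (0, 200] for the longest-protrusion
length, with a dedicated bin for exact zeros, and unit bins over 0–20 for
the count — and scores each seed against the target histograms with the
Bhattacharyya coefficient $BC = \sum_i \sqrt{p_i q_i}$, averaged over seeds
($BC_{llp}$, $BC_{np}$). Invalid threshold orderings
($s_{ret} \ge s_{exp}$, $s_{ret} \ge s_{birth}$ or $s_{exp} \ge s_{birth}$)
are rejected before any simulation runs.

The proposal engine is ordinary multi-objective Bayesian optimization over
the mixed nine-parameter space ($E_{protrusion}$ on a $10^{4..10}$ Pa log
grid, integer thresholds, real strain parameters, $s_{binary}$ on its
arithmetic grid): independent Gaussian-process surrogates (constant mean,
squared-exponential kernel on the normalized hypercube, hyperparameters by
marginal likelihood) per metric, a fresh random scalarization weight each
iteration, and expected improvement maximized over a candidate pool of
validity-passing random draws plus Gaussian perturbations of the best
incumbents. The balanced selection is the Pareto point maximizing
$\min(BC_{llp}, BC_{np})$, ties broken by the sum — our formalization of
"balance between both metrics". Any BO backend can be substituted behind
`propose_next()`.

## Synthetic in-vitro targets

Raw microscopy quantifications are not shipped; `generate_targets()`
emulates the published summary statistics instead: longest-protrusion
lengths from a truncated normal on (0, 140] µm whose *truncated* moments
equal 63.71/31.20 µm (the underlying location and scale are solved at
construction — naive truncation would shift the mean by ~1 µm), and counts
from the maximum-entropy distribution on 1..14 with mean 7.57 and sd 3.27
(the least-committal distribution given only two moments, a range, and a
"high dispersion" remark). The generator matches printed moments and
supports, not unpublished bar heights; one visible consequence is that its
modal length bin is (60, 80] rather than the reported (40, 60] — a truncated
normal cannot match both the moments and the mode, and the moments are the
tested quantities. Passing calibration tests against these targets therefore
demonstrates pipeline correctness and parameter recovery, not agreement with
the raw (unavailable) experimental distributions.

## Numerical choices and degenerate inputs

* FFT convolution with even extension is exact for the periodic/reflective
  boundary; kernels wider than the grid are rejected.
* Tau-leap rejections halve $\tau$; the SSA fallback interval is the floor
  length ($10^{-3}$ s), capped by the remaining window.
* R-level Poisson draws beyond integer range are treated as rejections;
  any such draw necessarily exceeds the conserved totals, so the compiled
  and reference backends agree exactly.
* All-zero propensities freeze the chemistry for the rest of the window
  (absorbing state); all-zero allocation weights are an error when events
  must be placed, and no-event windows deposit nothing.
* A full free retraction ($\varepsilon^f = -1$) kills the protrusion
  directly — the matrix constraint cannot rescue a collapsed configuration.
  A length update landing at or below $10^{-9}$ µm also kills. Dead
  protrusions are dropped from all statistics and never revived; a birth at
  the same site is a new identity.
* Ensemble seeds derive from the master seed by a fixed affine ladder below
  $2^{31}$, so member $i$ is identical regardless of ensemble size.

## Problem sizes in the test suite

The packaged studies are sized for a single CPU: distributional
leap-vs-SSA checks run on a 1/100-count system (1000 replicates for means,
600 for the Kolmogorov–Smirnov comparison); the calibrated ensemble runs
20 seeds at the default grid; the chemotaxis sweeps run 20 shared seeds per
condition on a 24×12 grid; and the self-recovery study runs ten independent
repeats of a 60-iteration calibration at 5 simulations per evaluation on a
24×12 grid with a 2-hour horizon. These are the package's standard reduced
problem sizes; all are configuration arguments, not constants.

## Known limitations

* With every printed constant applied literally and the documented defaults
  for the unprinted ones, the calibrated ensemble's pooled
  longest-protrusion statistics run high — roughly twice the published
  in-silico mean, with a correspondingly larger spread — while the
  protrusion-count mean lands within ~10%. The length scale is set by the
  calibrated amplitude $\alpha_{exp} = 0.14$ mm against the kinetics-derived
  $\delta s$ scale; no remaining free parameter moves it without touching
  quantities the model pins elsewhere. `scripts/acceptance.R` recomputes
  these statistics from scratch so the discrepancy is visible, not hidden.
* The chemoattractant profile is static (consumption neglected); ECM
  remodeling, anisotropy and heterogeneity are out of scope, as is traction
  from non-leading protrusions.
* The flattened-chart geometry ignores metric distortion near the poles;
  allocation weights are chart-uniform by design to avoid an artificial
  equatorial band.
* The culture-medium concentration for the calibration scenario is stated
  only qualitatively in the source material ("very low and fixed"); the
  default 0.05 µM is arbitrary and configuration-exposed. Receptor binding
  saturates at any realistic dose under the literal $k_1$, so this choice
  affects allocation weights far more than total signal.
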