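---
title: "A kinetic model coupling Wnt/beta-catenin signaling, N-glycosylation, and E-cadherin adhesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model coupling Wnt/beta-catenin signaling, N-glycosylation, and E-cadherin adhesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcnsim)
```

## The regulatory network

Epithelial cells balance proliferation and cohesion through three
intertwined pathways that share beta-catenin as a regulatory hub. In the
absence of Wnt3a, cytoplasmic beta-catenin is captured by the destruction
complex (axin, APC, GSK-3beta), phosphorylated, and degraded. Wnt3a binding
to the LRP5/6 co-receptor recruits the Axin/GSK3 unit to the membrane,
depleting the destruction complex; beta-catenin accumulates, partners with
TCF, and activates target genes — among them *DPAGT1*, which encodes GPT,
the first glycosyltransferase of protein N-glycosylation. GPT in turn sets
the N-glycosylation extent of E-cadherin: heavily glycosylated E-cadherin
makes unstable adherens junctions, and glycosylation of the Wnt machinery
itself (LRP5/6 maturation) feeds back on signal strength. `rcnsim`
implements this network as a 26-process reaction scheme over 24 state
variables (20 concentrations plus four per-pool E-cadherin adhesivity
factors) in MDCK-like units: concentrations in nM, time in minutes
(reported in hours).

Processes 1–10 cover Wnt/beta-catenin signaling and beta-catenin turnover,
11–19 *DPAGT1* induction and N-glycosylation (including LRP5/6 synthesis
and GPT-dependent maturation), and 20–26 E-cadherin synthesis, recycling
through ER, membrane, endocytic recycling compartment (ERC), and adherens
junction (AJ) pools. Rate laws follow fixed conventions: mass action
`k X Y - k_-(X/Y)` for binding, constant synthesis rates, first-order
conversion and transport, and a basal-free Hill law for transcription,

$$ v_{12} = T_{max} \frac{c^n}{K_{TmRNA}^n + c^n}, $$

with `c` the beta-catenin/TCF complex. Any basal *DPAGT1* expression is
absorbed into initial conditions; the Hill coefficient defaults to 2.

## Adhesivity factors

Each E-cadherin pool carries an adhesivity factor `sigma` in [0, 1], the
inverse of its N-glycosylation extent (1 = least glycosylated, most
adhesive). Transported pools inherit adhesivity by flux-weighted mixing,

$$ \frac{d\sigma_{dest}}{dt} = f_{gain} (\sigma_{source} - \sigma_{dest}), $$

where `f_gain` is the incoming flux divided by the pool concentration (a
small floor of 1e-9 nM guards empty pools, giving the prose "fraction of
incoming E-cadherin" a well-defined instantaneous rate). ER E-cadherin is
synthesized rather than transported; its adhesivity relaxes toward a
Michaelis–Menten glycosylation target set by GPT,

$$ \frac{d\sigma_{ER}}{dt} = f_{gain}\left[\left(1 - \lambda
  \frac{GPT}{K_M + GPT}\right) - \sigma_{ER}\right], $$

with the lumped extent `lambda = V_max t / G_max <= 1` treated as a single
constant (`t` a fixed ER residence time, not simulation time); `lambda > 1`
is rejected at construction since it would drive the target negative at
saturating GPT. Because the mixing law is a convex relaxation and the ER
target lies in [0, 1], every `sigma` remains in [0, 1] for all time — a
property the test suite checks under parameter stress.

Junction kinetics couple to adhesivity linearly: assembly
`k_24 = c_24 sigma_M` and disassembly `k_-24 = c_24 (1 - sigma_AJ)` — the
only monotone linear forms that stay nonnegative on the admissible range.
A single coupling scale `c_24` parameterizes process 24: the model's
published counts (35 parameters in total, 33 swept in sensitivity
analysis, 32 of them tabulated) admit exactly one reaction-24 constant, so
a second independent slope is not identifiable and was not introduced.

## Reduction to a DAE system

Processes 1, 2, 6, 8 and 11 (receptor binding, Axin/GSK3 recruitment,
beta-catenin capture and phospho-release, beta-catenin/TCF binding) are
fast relative to synthesis, transport, and degradation, and Wnt3a, APC,
TCF, and the Axin/GSK3 complex are expressed constitutively. Imposing the
five rapid equilibria and four conservation laws turns the 24-variable ODE
system into 15 differential equations plus 9 algebraic relations.

Internally the 15 differential variables are *fast-invariant totals*
(e.g. total non-phospho cytoplasmic beta-catenin = free + destruction-
complex-bound + TCF-bound) rather than free species: this is the exact
slow-manifold reduction, and it is what makes the reduced trajectories
track the full mass-action system to better than 1% when the fast
reactions are given explicit rates a thousand-fold above the slow ones
(`ode_rhs()` provides that full system; the test suite performs the
comparison). Resolving free species from the totals uses closed-form
quadratics (written in cancellation-safe form) and two small damped fixed
points; residuals of all nine algebraic relations are held below 1e-9
relative.

Steady states are found by damped Newton iteration with a numerical
Jacobian, falling back to stiff relaxation (`deSolve::lsoda`, rtol 1e-8,
atol 1e-10 nM) when Newton leaves the physical branch; frozen subsystems
(identically zero rows) are excluded from the Newton solve so degenerate
parameter sets remain solvable. Time courses use the same stiff
integrator. The default output grid is every 100 min over the first
900 min plus 12-h points from 24 h to 72 h; steady-state detection uses
the earliest time at which every differential variable satisfies
`|dx/dt| / (|x| + 1e-6) < 1e-4` per hour, evaluated on a dense 6-min grid
with log-linear refinement.

## Reference parameters

The full parameter set comprises 31 kinetic constants and 4 conserved
totals. The supplementary sources that tabulate the original values are
not distributed with the extracted text, so `reference_parameters()`
derives a set by the same constraint-based procedure the study describes:

* the Wnt/beta-catenin block is anchored to the published reduced models
  of canonical Wnt signaling (beta-catenin synthesis 0.423 nM/min, APC
  total 100 nM, TCF total 15 nM, beta-catenin/TCF dissociation constant
  30 nM, Axin/GSK3 total 30 nM of the same order as the Wnt ON stimulus so
  receptor sequestration can relieve degradation);
* the remaining constants are fixed by the reference behaviors: a Wnt OFF
  cytoplasmic beta-catenin level of ~21 nM; a 3.0-fold rise of active
  beta-catenin upon stepping total Wnt3a from 1 to 28.062 nM (the
  measured response); GPT induction of ~1.3-fold with AJ abundance and
  adhesivity falling on activation; detected steady state at 35 h; and
  E-cadherin inventory turnover of ~4 h consistent with tagged-cadherin
  chase timescales.

Two systems-level features emerged as the binding constraints on the slow
timescale and were set deliberately: the E-cadherin inventory turnover
(total cadherin over synthesis flux) and the gain of the positive feedback
loop GPT -> LRP5/6 maturation -> Axin/GSK3 sequestration -> beta-catenin.
GPT-dependent maturation is therefore bimolecular (`k_17 GPT LRP_i`),
partially saturated at the reference point — without GPT in that rate,
N-glycosylation could not modulate Wnt signal strength at all. Process 21
(ER-to-membrane export) is a first-order transport constant that keeps its
historical name `K21`.

The calibration module makes the procedure reproducible:
`constraint_report()` checks any parameter set against the behavioral
targets, and `fit_parameters()` adjusts chosen constants by seeded
multi-start Nelder–Mead least squares on log-scale residuals with box
bounds of a factor 100 — wide enough to be uninformative, in log space
because rate constants are positive and span decades.

## Sensitivity analysis

Fold change — the ratio of a molecule's concentration after Wnt3a
stimulation to its Wnt OFF equilibrium value — is the system's response
metric. Local sensitivity to parameter `i` at scale factor `F` is

$$ S_{ij} = \left| \frac{(X^{Wnt}/X^0)_{ij} / (X^{Wnt}/X^0)_{ip} - 1}{F - 1} \right|, $$

averaged over the factor grid and then over all 24 variables for a global
ranking. The sweep spans two decades on a uniform log grid, 9 points per
decade (18 factors; F = 1 excluded where the ratio is undefined), dense
enough that halving the grid moves the averages by well under the
published table's precision. The absolute value is applied because the
tabulated sensitivities are nonnegative. Both steady states are recomputed
per cell (Newton, warm-started from the neighboring factor); fold changes
are evaluated at steady state, which the 72-h horizon reaches in the
reference condition. Total Wnt3a is excluded (it defines the metric) and
the Hill coefficient too (its power form distorts the linear scaling and
reduced models showed the system insensitive to it); cells with invalid
parameterizations (e.g. `lambda F > 1`) or non-convergent steady states
are dropped from averages with a warning. `classify_impact()` flags a
parameter as high (low) impact for a variable when its sensitivity is at
least twice (at most half) the variable's mean — flags invariant to global
rescaling.

With the reconstructed reference set the ranking reproduces the reported
zero sensitivities of E-cadherin recycling (the export and recycling
constants `K21` and `k23` drop out of steady-state fold changes exactly,
because linear transport cancels in ON/OFF ratios) and the reported
pathway ordering — signaling most influential, then N-glycosylation, then
adhesion. The identity and magnitude of the single top-ranked parameter,
by contrast, depends on fine structure of the original equations (notably
where destruction-complex flux saturates in beta-catenin) that the
available text does not pin down; in this reconstruction the conserved
Axin/GSK3 total ranks first and beta-catenin synthesis eleventh. The
acceptance suite states the published expectation and reports the
discrepancy rather than masking it.

## Condition presets

Four presets mirror the experimental design: `reference` vs
`dysregulated` — the latter modeling ICG-001-type inhibition of
beta-catenin/TCF-dependent transcription as a doubling of the dissociation
constant `K11` — each in Wnt OFF (total Wnt3a 1 nM) and Wnt ON
(28.062 nM). Dysregulation lowers *DPAGT1* output, de-glycosylates
E-cadherin, and raises both junction abundance and adhesivity in both Wnt
states, the direction seen biochemically.

## Collective-motility metrics

The motility module consumes PIV-style velocity fields (regular grids of
2-D vectors; wound closure along +x) and quantifies collectivity:

* **Correlation profile and length.** Lateral fluctuations (y-components
  minus their frame mean) are correlated over binned pair separations with
  per-bin normalization, so C(0) = 1 and the profile is invariant to
  drift and speed rescaling. Two length estimators are provided: the
  experimental convention — first zero crossing of C(r), falling back to
  C < 0.05 — and a log-linear exponential-decay fit over the contiguous
  initial decay with a free intercept (absorbing uncorrelated noise).
  The threshold convention reports where correlation becomes negligible
  (about 3 decay lengths for an exponential profile); the fit recovers
  the decay length itself and is the right tool for generator round
  trips. Frames from the first hour after scratching are excluded;
  lengths are averaged over the remaining recording (27 of 28 frames at
  the default 30-min cadence over 15 h).
* **Movement-angle maps.** Per-frame occupancy histograms of the angle
  between each vector and the wound-closure direction, 72 bins of 5
  degrees, rows normalized to 1, zero vectors excluded and counted.
* **Leading-edge speed.** The front is the average foremost detected
  fluorescence per row; speed is the field-of-view traversal distance
  over time (slope fallback, flagged, when the front never reaches the
  edge), at the default calibration of 1.125 um/px and 30 min/frame.

## Synthetic data

All inputs are generated by seeded, reproducible code. Velocity fields
superpose a mean wound-directed flow with per-vector directional noise
and a lateral Gaussian random field with exponential spatial covariance,
synthesized spectrally (FFT filtering of white noise on a 2x padded grid)
for an exact target covariance. Front masks advance at a known speed with
per-row jitter. Fold-change observations are simulated from a known
parameter set and perturbed lognormally for calibration round trips. The
generators emulate the statistical structure of PIV output and
fluorescence fronts — spatial correlation, directional spread, front
noise — but not optical artifacts, cell-shape texture, uneven
illumination, or PIV window-correlation failures; passing recovery tests
therefore validates the estimators, not the upstream imaging pipeline. On
a 24 x 24 grid spanning 576 um, finite-window mean subtraction biases the
fitted 50-um correlation length low by roughly 10–15%, within the
per-recording sampling spread; recovery is asserted at 25%.

## Numerical choices and degenerate inputs

Tolerances: integrator rtol 1e-8 / atol 1e-10 nM; Newton convergence at
scaled residual 1e-11 per minute; algebraic residuals below 1e-9.
Tie-breaks and guards: empty pools get the 1e-9 nM `f_gain` floor;
adhesivity is clamped to [0, 1] and concentrations to nonnegative inside
the integrator (drift beyond 1e-8 is an error, not a clamp); destruction-
complex pools exceeding total APC or Axin/GSK3 raise degenerate-parameter
errors; `lambda > 1` is rejected. Problem sizes used throughout the tests
and the acceptance script — 18-factor sweeps over 33 parameters, 72-h
horizons, 24 x 24 x 28 velocity fields — were chosen so each analysis
completes in minutes on one core while leaving grid-halving checks
unchanged at reported precision.

## Known limitations

* The original supplementary equation list and parameter table are not
  shipped with the extracted text; the scheme here is a constraint-based
  reconstruction from the figure stoichiometry and stated rate-law
  conventions. Equations reconstructed this way are flagged in comments.
* The published claim that junction abundance equilibrates faster than
  adhesivity is not reproduced: with junction rates slaved to the
  adhesivity factors (`k_24 = c_24 sigma_M`, `k_-24 = c_24 (1 -
  sigma_AJ)`), the AJ pool necessarily tracks `sigma_AJ` and its relative
  settling tail is at least as long. Reproducing the ordering would
  require structure (for example adhesivity-dependent transport, or
  junction dynamics driven by beta-catenin availability) that the
  available text does not specify.
* The single top-ranked sensitivity parameter is reconstruction-dependent
  (see above).
* Experimental speed and correlation values from the wound assays are
  wet-lab measurements outside the model's reach; the motility module is
  validated against synthetic fields with known ground truth instead.
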