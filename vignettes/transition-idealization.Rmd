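---
title: "Segmentation-based idealization of unitary current traces: models and methods"
author: "patchseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-based idealization of unitary current traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchseg)
```

## The problem

Whole-cell recordings of large-conductance channels such as connexin
hemichannels show rare, abrupt unitary current steps riding on a slowly
drifting background current, with more than one conductance level per
channel (a fully open *main* state near 217 pS and a *subconductance* or
residual state near 80 pS at the conditions this package's defaults
emulate).  Manual idealization of such traces is slow and biased, while
hidden-Markov approaches require dwell-time and conductance assumptions
that are exactly what one wants to measure.  `patchseg` implements a
*segmentation-based* alternative: locate level changes directly, fit each
transition's amplitude and speed, and let the event set itself define the
baseline to be removed.

Unitary conductance is always derived from the fitted current step as
$\gamma = \Delta i / V_m$ (pA/mV, reported in pS).

## The pipeline

Per trace, `analyzeTrace()` performs:

1. **Running median** (window `tMF`, default 0.3 s — the slowest expected
   transition time).  Unlike a low-pass filter, the median suppresses
   noise while preserving step amplitudes and keeping drift
   distinguishable from gating.
2. **Candidate detection.**  An edge appears in the median output as a
   monotone ramp, so same-sign first differences are accumulated into
   monotone runs and each run whose net amplitude exceeds the conductance
   threshold (default 60 pS = twice the 30 pS background-noise SD of the
   emulated recordings) becomes one candidate, timed at its steepest
   point.  Two practical details matter.  First, the running median moves
   in order-statistic jumps, so a light boxcar (`tMF/6`) is applied before
   differencing — otherwise single-sample jitter shatters each ramp into
   dozens of runs.  Second, same-sign runs separated by less than
   `mergeGap` (10 ms) *and* whose steepest points lie within
   `minSeparation` (0.15 s) are coalesced: these are fragments of one
   noise-split edge.  We deliberately do **not** merge all candidates
   within `minSeparation`, because genuinely distinct stacked events
   frequently occur within 150 ms of each other and a time-distance-only
   merge would silently delete them.
3. **Total variation denoising** of the raw trace
   (`min ½Σ(y−x)² + λΣ|Δx|`), solved by majorization–minimization
   iterative clipping on the dual.  With the default λ = 10⁴ (pA scale)
   and 30 iterations the solver is intentionally under-converged: the
   clip bound is never active and the iteration acts as a short
   edge-preserving diffusion whose strength is set by the iteration
   count.  This is the regime the default analysis uses; with a large
   iteration budget and a tolerance the same routine converges to the
   exact TV proximal operator, which is how it is validated against the
   bundled exact taut-string solver (`tvTautString()`, a direct
   shortest-path-through-tube construction certified in the tests by the
   dual optimality conditions).  λ is applied to currents in pA at native
   sampling and is therefore scale-dependent; it is exposed as a
   parameter.
4. **Refinement.**  Each candidate time is moved to the maximal
   sign-consistent derivative of the TVD trace within ±0.3 s.  The
   derivative is estimated with a symmetric difference over ±10 ms
   (`refineStencil`): single-sample differences lose slow (≥10 ms time
   constant) edges to denoised-noise wiggles, while the wide stencil
   leaves the argmax at the edge center.
5. **Error-function fits.**  Each transition is fitted as
   $f(t) = A\,\mathrm{erf}((t-t_0)/B) + C$ over ±150 ms (window size =
   maximum transition time).  The transition amplitude is $a = 2A$, the
   transition time constant $t_c = B$, and $C$ the local mid-level.  If
   another event lies in the window, the window is shrunk to the midpoint
   towards it; events closer than 20 samples are fitted jointly as a sum
   of two erf terms to avoid amplitude cross-contamination.  The center
   $t_0$ is fitted (initialized at the refined time, bounded inside the
   window) because refined times are quantized to the sampling grid and a
   fixed, half-sample-wrong center measurably biases $A$ and $B$ for fast
   edges; `fitCenter = FALSE` restores the fixed-center variant.  Initial
   values are deterministic (half the local level difference, B = 1 ms
   with a small ladder of restarts, C from the pre-edge mean), making the
   whole pipeline reproducible bit-for-bit.
6. **Baseline isolation.**  The signed fitted amplitudes, rendered as erf
   edges at their fitted time constants, are accumulated into an
   idealized trace; raw − idealized is fitted by nonlinear least squares
   to four drift families — single exponential $a(1-e^{-x/b})+c$, double
   exponential, logarithmic $a\ln(x+c)+b$, and linear — and the
   lowest-AIC family wins (the choice rule is ours; all fits are kept,
   and a single family can be forced).  The fitted drift is subtracted
   from the raw trace and the full detection chain re-runs on the
   corrected trace, repeating until the event set is stable (max 5
   cycles, our stopping rule).  The final state is always recomputed by a
   canonical two-round pass from the event *times* alone, so that manual
   edits compose exactly (see below).
7. **Metrics.**  NPo = cumulative open time / recording time with the
   open–closed discriminator half-way between closed and fully open
   levels; stacked openings count k-fold.  Events are classified into
   states by the one-SD interval rule around the component means;
   per-trace transition counts are normalized to a 30 s window.

### Headless manual editing

`addEvent()` searches the steepest sign-consistent TVD derivative within
a ±500-sample window of the requested time, fits and inserts the event
(provenance `"manual"`), and recomputes everything downstream; additions
in regions without an edge above 5× the robust derivative noise are
refused.  `removeEvent()` is its inverse, and because the final state is
a deterministic function of the event keys, *add-then-remove is exactly
the identity*.  Every edit lands in an audit log that `replayEdits()` can
re-apply to the raw trace.

Sub-threshold events (below 60 pS) are invisible to automated detection
by design — the threshold serves the baseline-isolation pass — and enter
the analysis through this manual route.

## The synthetic-data generator

`simulateTrace()` draws, per channel, alternating closed and open
sojourns; openings arrive as Poisson attempts while closed, with the
attempt rate solved so that the expected number of transitions per trace
matches `transitionRate × duration`.  Each opening draws its conductance
from the targeted state's Gaussian (defaults: main 217 ± 66 pS, substate
80 ± 28 pS, substate probability 5.3% for the control profile), its
paired closing returns by the same amplitude, and every edge is rendered
as an erf step with a time constant drawn from an exponential of mean
5.2 ms truncated at 300 ms.  Gaussian noise is specified in pS
(default 30) and converted through $V_m$; drift, when enabled, comes from
the same four families the baseline stage fits, with default coefficients
giving roughly three main-state amplitudes of drift per 30 s trace.
Events are confined to a 0.5 s margin inside the trace.

Two generator choices deserve emphasis:

* **Sojourn floor.**  Open dwells and closed gaps are drawn as
  `minSojourn + Exp(mean − minSojourn)` with `minSojourn = 0.4` s and
  mean 1 s.  A plain exponential puts a sizeable fraction of events
  inside pulses shorter than `tMF/2` = 150 ms, which a 0.3 s median
  filter removes *outright* — no detector operating on the median output
  can see them.  The floor keeps the simulated gating inside the method's
  resolvable regime; with `minSojourn = 0` the generator produces flicker
  gating whose brief events must be added manually, which is exactly the
  workflow the edit API models.
* **What the generator does not emulate:** amplifier/Bessel frequency
  response, capacitive transients, seal-leak physics, open-channel excess
  noise, or state-dependent kinetics.  Passing tests on synthetic cohorts
  therefore demonstrates correctness of the *analysis machinery* under
  the stated statistical model, not performance on every pathology of
  real recordings.

Reproducibility: a cohort derives per-trace seeds from one master seed by
a fixed rule (`seed + i·100003 mod 2147483629`), so any member can be
regenerated in isolation.

## Cohort statistics

Conductance histograms are decomposed into Gaussian components.  For a
single dominant peak the default is least squares on the binned,
max-normalized histogram (the way such distributions are usually
displayed).  For two components the default is the mixture
maximum-likelihood fit (deterministic EM): at a few hundred events — the
scale of a realistic treated-condition cohort — the binned least-squares
objective is nearly flat along a ridge that trades substate width against
main-state location, and it routinely collapses the minor component's SD
several-fold while displacing the main mean by 10–20%.  We measured this
on generative draws with no pipeline involved, and kept the histogram
method available (`method = "histogram"`) for figure-style fits.  Event
sets produced by automated detection exclude conductances below the
60 pS threshold; two remedies are provided.  `truncateBelow` switches the
MLE to the left-truncated mixture likelihood, and — the route the
validation uses, mirroring the semi-automated workflow the method is
designed around — `annotateMissedEvents()` re-inserts censored events
through the manual-add machinery at their known locations on simulated
data, after which the ordinary mixture fit applies.

One caution from our own validation: with components as overlapped as
80 ± 28 and 217 ± 66 pS, the substate component *mean* of an
unconstrained two-component fit carries an intrinsic uncertainty of about
4 pS (≈5%) at a ~650-event cohort — replicate studies show the global
MLE itself can sit >10 pS off when the cohort's binomial substate share
fluctuates low.  Single-cohort substate means should therefore be quoted
with that uncertainty; the pipeline contributes almost nothing to it
(per-event amplitude errors are ~2 pS).

Transition-kinetics distributions are fitted with mono- and biexponential
models and compared by AIC; the default estimator is again raw-value
maximum likelihood (multi-start EM for the mixture), with the binned
least-squares decay fit available for presentation.  At realistic event
counts (≈650) the slow component of a 2:1 fast/slow mixture carries an
intrinsic estimator SD around 14%, so single-cohort slow-τ estimates
should be read with that uncertainty in mind.

Substate prevalence is summarized as the AUC ratio
$\mathrm{AUC}_{sub}/(\mathrm{AUC}_{full}+\mathrm{AUC}_{sub})$ and
compared across conditions as a fold-change; when a reference condition
shows no separate substate peak, a fixed-shape (mean and SD frozen)
substate template is amplitude-rescaled to the reference histogram
(`scaleSubstateTemplate()`) and flagged as such.  Count-based per-trace
summaries (`transitionFolds()`) are reported alongside, because AUC- and
count-based substate fractions need not agree.

Two-condition kinetics comparisons per state class use the two-sample
Wilcoxon rank test from base R; classes with fewer than five events per
side are summarized without a test.

## Numerical choices and degenerate inputs

* Median filter: shrinking (truncated) windows at the trace ends;
  even-sized windows take the midpoint of the two central order
  statistics.  Candidates within `tMF/2` of the ends are discarded — the
  tiny end windows are order statistics of too few samples to threshold
  meaningfully.
* TVD: clip bound λ, dual step 1/4 (the tight bound on the dual
  operator's spectral norm); λ = 0 returns the input bit-identically.
* erf fits: B bounded in (half a sample period, 0.3 s); non-convergence
  after a restart ladder falls back to the local level difference with
  the fit flagged and `tc` missing.
* Baseline fits: evaluated on at most 20 000 evenly spaced samples
  (drift is slow by definition); a family that fails to converge is
  skipped; if all fail, a constant (mean) baseline is used with a
  warning.  The log family's offset is kept positive by bounds.
* Histogram fits: degenerate all-identical inputs return an SD floored at
  the bin width, flagged; mixture EM responsibilities are floored to
  avoid 0/0 on far outliers.
* NPo: warns and flags when the open level is within three noise SDs of
  the closed level.

## Problem sizes used in validation

The bundled validation works at desk scale: single traces of 10–30 s at
4 kHz for pipeline properties; cohorts of 15–50 traces for
distribution-recovery checks (a few hundred transitions, matching the
per-condition event counts of realistic datasets); 200-replicate draws
for estimator-bias and model-selection frequencies; TV-solver
equivalence on ≤ 200-sample signals across a λ grid, where the iterative
solver is run to convergence and compared with the exact taut-string
construction at 10⁻⁶.

## Known limitations

* Events shorter than half the median window require manual addition;
  this is intrinsic to median-based candidate detection.
* The 60 pS threshold censors the lower tail of the substate
  distribution; the truncation-aware MLE corrects the fitted component,
  but individual sub-threshold events are simply absent from event
  tables unless added manually.
* λ's absolute default is tied to the pA scale at 4 kHz; traces in other
  units need a rescaled λ.
* NPo with multiple channels uses the nominal k-fold threshold rule;
  channels of unequal conductance are not disambiguated.
* The reanalysis loop has no proven fixed point; oscillating event sets
  are returned after 5 cycles with a non-convergence flag.
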