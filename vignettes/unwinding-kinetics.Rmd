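---
title: "Modeling and inferring repetitive helicase unwinding kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and inferring repetitive helicase unwinding kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The kinetic model

`unwindr` treats one surface-immobilized RNA duplex observed by two-color
smFRET as a continuous-time Markov process with five substeps per
unwinding cycle:

* **B** (binding wait): the delay between reagent addition and protein
  binding, exponential with rate `k_on * [RHA]`. Binding is detected
  through protein-induced fluorescence enhancement (PIFE): the total
  intensity jumps by the factor `pife_gamma` while protein is bound.
* **A** (activation): a lag at low FRET between binding and the first
  unwinding cycle, rate `k_act`. Under the wild-type defaults this is the
  slowest substep, i.e. the rate-limiting step of the reaction.
* **U** (unwinding): FRET rises gradually from `E_low` to `E_high` as the
  unwound strand coils and brings the dyes together. The dwell is
  exponential with rate `k_unw * [ATP] / (Km_atp + [ATP])` — only this
  substep senses ATP, through Michaelis-Menten scaling — and the FRET ramp
  is modeled as linear in time across the dwell.
* **S** (stalling): a high-FRET pause, exit rate `k_stall`. Leaving the
  stall triggers an instantaneous rewind (the duplex rezips as the enzyme
  slips back), dropping FRET back to `E_low` within a frame.
* **R** (reactivation): a second low-FRET lag, rate `k_react`, before the
  next cycle.

Two hazards compete with every bound dwell: dissociation (`k_off`, total
intensity returns to the unbound level) and photobleaching (`k_bleach`,
both channels drop to background). After each completed stall the strands
fully separate with probability `p_sep`; the labeled strand then leaves
with the dyes, so separation is also a drop to background and — by
design — distinguishable from bleaching only through the simulator's
ground truth. A molecule cycles repetitively (typically a median of 2–10
cycles under the wild-type defaults) until separation, dissociation or
photobleaching ends the event. Dissociation is treated as absorbing for a
molecule: one binding event per trace, which matches how events are
analyzed downstream.

Observation model: frames integrate for `frame_s` (default 0.1 s); each
frame reports the state at its midpoint; `I_A = E * T` and
`I_D = (1 - E) * T` receive independent per-channel Gaussian noise of SD
`sigma_noise` with no clipping, so raw intensities can be slightly
negative. Donor leakage, gamma correction and blinking are deliberately
not modeled.

## Default parameters and what is assumption vs. measurement

All defaults live in `inst/extdata/preset_params.yaml` and are documented
in `?sim_params`. Only a few are anchored to published measurements for
RNA helicase A: the association constant `k_on = 2.61e6 /M/s`, the
Michaelis constant `Km_atp = 26 uM`, the 100-ms framing, and a 37 °C
acceleration inside the reported 2–5x band (`temp_factor = 3`, applied
uniformly — including to binding, since all substeps speed up at 37 °C,
plausibly through faster diffusion and ATP turnover). Every other number
is a package assumption chosen once so that the qualitative structure
holds: activation slowest (`k_act = 0.05 /s` against `k_unw = 0.8 /s`,
`k_stall = 0.5 /s`, `k_react = 0.3 /s`), weak competing hazards
(`k_off = k_bleach = 0.002 /s`), `p_sep = 0.15` so that the cycle count
per event has median in the 2–10 range, and FRET levels `E_low = 0.2`,
`E_high = 0.8`. The `delta_dsRBD` preset encodes the dsRBD-truncation
phenotype: lower `k_on`, higher `k_act` (activation disinhibited), equal
`k_unw`, much higher `k_off`, and `p_sep = 0.9`, which makes single-cycle
events followed by dissociation the norm.

GC content scales unwinding and stall-exit exponentially,
`k * exp(-coef * (gc - 0.5))`, so AT-rich substrates unwind markedly
faster and stall slightly shorter; only the direction and the relative
prominence of the unwinding effect are constrained by observation, the
coefficients (5 and 1.5) are assumptions. Annealing is modeled at the
field-of-view level: each molecule anneals at an exponential rate chosen
by condition (zero without protein; a binding-induced rate without ATP; a
faster unwinding-induced rate with ATP), with per-variant preset rates
defined at the concentrations where the variants are compared (40 nM wild
type, 320 nM mutant).

## The analysis chain

`compute_fret()` forms `E = I_A / (I_D + I_A)` and `T = I_D + I_A` per
frame, and masks frames invalid from the first sustained (3-frame) run of
at-floor totals; the mask is monotone. Raw FRET is kept for segmentation;
a clamped copy feeds histograms.

`detect_intensity_steps()` finds binding and dissociation as change
points of the total intensity by binary segmentation with the
standardized CUSUM statistic: noise scale from the median absolute first
difference, split positions from the exact two-mean least-squares argmax,
and a Bonferroni-style threshold (`alpha`, default 0.01 per trace).
Offline change-point detection was chosen over a fixed-window sliding
test because its power grows with segment length, which matters for
binding events close to the start of a movie; any method passing the
simulator-oracle tests could be substituted. Up-steps are classified as
binding; down-steps to background as end of signal (separation or
bleach); intermediate down-steps as dissociation. A molecule that binds
before the third frame has no unbound baseline and cannot yield a
binding step — such events are flagged by their absence rather than
guessed. Traces with a second up-step before a down-step are flagged
`multi_binder` instead of silently filtered.

`segment_substeps()` idealizes each bound interval. Median-filtered FRET
(width 3, used for classification only, never for dwell arithmetic) is
thresholded at the mid band to find unwinding/stall excursions; runs
split by one-to-two-frame dips that never return to the low level are
merged (noise dips), while dips that touch the low level are genuine
rewinds. Within each excursion the stall level is estimated from the top
of the high band (a plain band median would be dragged down by slow-ramp
frames), and the two unwinding boundaries come from intersecting a line
fit through the mid-band ramp frames with the event's low and high FRET
levels — exact on noiseless data — followed, when noise is present, by a
local grid refinement of a plateau–ramp–plateau model against the raw
FRET. Runs touching the end of the event are declared stalls only if
capping the fitted ramp at the stall level explains the data strictly
better than letting it continue to rise; otherwise they are censored
unwinding. The first low-FRET dwell of an event is activation, later ones
reactivation (a purely positional rule); the rewind drop is assigned zero
duration with its frames attached to the following reactivation dwell.
The label grammar `A (U S R)* (U S)?` holds for every uncensored event.

Dwell bookkeeping: `extract_dwells()` emits one record per segment plus
the binding wait (time from acquisition start, or from a configurable
reagent-addition offset `t0` for preloading designs). A segment touching
the event's terminal boundary is censored, with one exception: a stall
that ends in an observed drop has completed its exit and is uncensored.
Dwells shorter than half a frame (possible after quantization of
sub-frame excursions) are floored at `frame_s / 2`, a midpoint imputation
of an unresolved dwell; this is why the dwell table guarantees positive
rather than strictly frame-sized dwells. `count_cycles()` counts entered
stalls (U–S pairs), so a final stall cut short by dissociation still
counts its cycle.

Rates: the exponential MLE `1/mean` over uncensored dwells, SEM by the
delta method (`rate/sqrt(n)`) with a seeded bootstrap option. Censored
dwells are excluded and counted; with the default weak hazards the
resulting upward bias is a few percent at most, far below the sampling
error of realistic event counts, and the oracle tests quantify it. The
off rate is `1/mean` of total bound times over events ending in an
observed dissociation. Under the wild-type defaults most events end by
strand separation instead, so off-rate estimates rest on the minority of
dissociation-ended events and carry wide errors — which is also why they
are a flatness check, not a precision target. Curve fits use weighted
least squares: a zero-intercept line for binding rate vs protein
concentration (a binding rate must vanish at zero protein; a
free-intercept diagnostic mode exists), Levenberg–Marquardt for the
Michaelis–Menten and binding-isotherm fits with data-driven starting
values and explicit convergence/identifiability flags.

Annealing: counts of high-FRET molecules per snapshot become fractions
with Wilson intervals; the rate comes from fitting `1 - exp(-kt)`.
Because the snapshots count the same molecules cumulatively, the points
are strongly correlated and the naive fit covariance understates the
error; the standard error is therefore a parametric bootstrap over whole
fields, seeded deterministically from the data. An initial-slope estimate
is emitted alongside as a cross-check, and the enhancement factor is the
ratio of the with-ATP to the without-ATP rate with propagated error.
Whether published bar summaries of such assays are endpoint fractions or
fitted rates is ambiguous; both summaries are available here.

## Numerical choices and degenerate inputs

* Boundary resolution: all oracle tests hold segment boundaries to one
  frame. Excursions whose whole unwinding-plus-stall footprint spans
  fewer than about three frames sit below that resolution; the simulator
  ground truth shows they occur (exponential dwells reach zero) and the
  test comparator treats them as unresolvable rather than pretending the
  detector can see them.
* Zero-variance data: the CUSUM scan falls back to an exact mean-shift
  rule when the noise estimate is zero, so noiseless traces segment
  exactly; ramp line fits require a minimum rise per frame so that
  numerically zero slopes cannot extrapolate a crossing to infinity.
* Degenerate fits error or flag, never silently return numbers: all-censored
  dwell sets, all-zero annealing curves, saturating-only
  Michaelis–Menten designs and flat isotherms each produce either an
  informative error or a `degenerate`/`identifiable`/`converged` flag.
* Reproducibility: every simulation takes a seed; datasets derive
  per-molecule child seeds deterministically from the root seed and
  molecule index, so runs are byte-identical.

## What the simulator does and does not emulate

The generator reproduces the features the inference chain must cope
with: exponential substep dwells with competing dissociation and
bleaching, gradual FRET ramps with instantaneous rewinds, PIFE steps at
binding and dissociation, terminal strand separation, and additive
Gaussian camera noise at 100-ms framing. It does not emulate donor
leakage, gamma miscalibration, blinking, multi-level partial unwinding
amplitudes, sequence-explicit duplex energetics, spatial diffusion, or
multiple proteins engaging one molecule. Passing the recovery tests
therefore shows the estimators are correct for data generated by this
model at realistic noise, not that real data meet the model; on real
traces the un-modeled photophysics would first surface as extra apparent
steps or FRET levels, which the `multi_binder` flag and censoring
accounting are designed to expose rather than absorb.

## Problem sizes used by the test-suite studies

The simulation studies behind the package's tests use a few hundred
molecules per condition (for example 170 events for full five-rate
recovery, 45–80 molecules per grid point for concentration invariances,
2000 molecules per annealing field, 5000 per histogram population, and
200 dwells per concentration for the seeded Km and association-constant
recoveries), sizes chosen to match the scale of a realistic
single-molecule experiment while keeping each study's Monte Carlo error
well inside the tolerance it checks.

## Known limitations

Sub-frame substeps are unresolvable and surface as merged neighbors or
floored dwells; the A-versus-R distinction is positional, so an
unresolvable first cycle makes the following reactivation dwell look like
continued activation; separation and bleaching are indistinguishable
without ground truth, and a bleach that strikes mid-ramp can masquerade
as a completed cycle; off-rate estimates are noisy whenever dissociation
is rare relative to separation; and binding events within the first few
frames of a movie cannot be detected at all.
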