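# unwindr

Single-molecule FRET kinetics of repetitive RNA unwinding by RNA
helicase A (RHA/DHX9) — a simulator of the five-substep unwinding cycle
and the full inference chain that recovers its rate constants from
two-channel intensity traces.

## The problem

RHA unwinds short stretches of double-stranded RNA repetitively: one
enzyme binds (**B**), pauses in an activation state (**A**), unwinds so
that FRET rises gradually (**U**), stalls at high FRET (**S**), lets the
duplex rezip in a rapid rewind, reactivates (**R**), and starts over —
typically for several cycles before the strands fully separate and the
protein leaves. Protein binding and dissociation are visible as abrupt
total-intensity steps (protein-induced fluorescence enhancement). With
dwell times τ per substep the headline quantities are

* substep rates `k = 1/⟨τ⟩` with SEM `k/√n` (exponential MLE),
* the association constant `k_on` from the zero-intercept line
  `k_B = k_on · [RHA]` (≈ 2.61×10⁶ M⁻¹s⁻¹ for wild-type RHA),
* the ATP dependence of unwinding, `k_U = V_max·[ATP]/(K_m+[ATP])` with
  `K_m ≈ 26 μM`,
* the off rate from total bound times, cycle counts per binding event
  (median 2–10), temperature fold-changes (2–5× at 37 °C), and
* the annealing enhancement factor: the ratio of unwinding-induced
  (+ATP) to binding-induced (−ATP) annealing rates.

The package is for single-molecule biophysicists who want a
ground-truthed testbed for this kind of analysis: every stage — FRET
calculation, change-point detection of binding/dissociation/bleaching,
substep idealization with censoring, dwell-time rate estimation, curve
fits, annealing time courses — is exercised against a stochastic
simulator whose parameters are known, so estimator correctness is a
testable claim rather than a hope. See the vignette
(`vignettes/unwinding-kinetics.Rmd`) for the model, assumptions and
numerical choices.

## Worked example

Simulate one wild-type condition (40 nM RHA, 1 mM ATP, 100-ms frames)
and run the analysis chain:

```r
library(unwindr)

p  <- preset_params("wild_type")
ds <- simulate_dataset(p, condition(rha_nM = 40, atp_uM = 1000),
                       n_molecules = 60, duration_s = 150, seed = 7)
an <- analyze_traces(ds$traces)
an$rates
#> # A tibble: 5 × 6
#>   substep condition                              rate     sem     n n_censored
#> 1 B       wild_type_rha40nM_atp1000uM_RT_gc0.5 0.0931 0.0121     59          0
#> 2 A       wild_type_rha40nM_atp1000uM_RT_gc0.5 0.0526 0.00697    57          2
#> 3 U       wild_type_rha40nM_atp1000uM_RT_gc0.5 0.770  0.0454    287          5
#> 4 S       wild_type_rha40nM_atp1000uM_RT_gc0.5 0.456  0.0273    279          8
#> 5 R       wild_type_rha40nM_atp1000uM_RT_gc0.5 0.303  0.0198    234          5
median(an$events$n_cycles)
#> [1] 4
```

Reading the output: 59 of 60 molecules produced a detected binding event;
each substep's `rate` is the reciprocal mean of its uncensored dwells
(`n` of them; dwells cut short by dissociation, bleaching or trace end
are `n_censored`). The estimates bracket the generating values — binding
0.093 s⁻¹ vs `k_on·40 nM = 0.104`, activation 0.053 vs 0.05 (the
rate-limiting step), unwinding 0.77 vs 0.78 at 1 mM ATP, stalling 0.46
vs 0.5, reactivation 0.30 vs 0.3 — and a median of 4 unwinding cycles
per binding event falls in the experimentally typical 2–10 range.
Concentration series feed `fit_association_constant()` and
`fit_michaelis_menten()` (both with broom-style `tidy()`/`glance()` and
`autoplot()` methods), `simulate_annealing_field()` +
`estimate_annealing_rate()` + `enhancement_factor()` reproduce the
annealing comparison, and `run_pipeline()` drives the whole chain from a
YAML/`list` config (see `inst/scripts/run_pipeline.R` for a command-line
wrapper).

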