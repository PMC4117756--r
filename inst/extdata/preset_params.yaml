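# Default simulation parameters per protein variant.
#
# Only a few of these numbers are published measurements for RHA:
#   k_on    2.61e+06 M^-1 s^-1  (association constant, binding rate vs [RHA])
#   Km_atp  26e-6 M           (Michaelis constant of the unwinding substep)
#   frame_s 0.1 s             (camera integration time)
#   temp_factor within the reported 2-5x acceleration band at 37C
# Every other value is an ASSUMPTION chosen so that the reported qualitative
# orderings hold: activation is the slowest substep (rate limiting); the
# dsRBD-truncation mutant binds slower, activates faster, unwinds at the same
# rate, dissociates faster, and typically completes a single cycle; wild-type
# events span a median of 2-10 unwinding cycles. Units: rates s^-1 except
# k_on (M^-1 s^-1); concentrations molar; intensities arbitrary units.
wild_type:
  k_on: 2.61e+06
  k_act: 0.05
  k_unw: 0.8
  Km_atp: 2.6e-05
  k_stall: 0.5
  k_react: 0.3
  k_off: 0.002
  p_sep: 0.15
  E_low: 0.2
  E_high: 0.8
  pife_gamma: 1.5
  I_total: 200.0
  sigma_noise: 10.0
  k_bleach: 0.002
  frame_s: 0.1
  temp_factor: 3.0
  gc_coef_unw: 5.0
  gc_coef_stall: 1.5
  gc_ref: 0.5
  k_anneal_bind: 2.0e-03
  k_anneal_unwind: 1.0e-02
delta_dsRBD:
  k_on: 6.0e+05
  k_act: 0.25
  k_off: 0.08
  p_sep: 0.9
  k_anneal_bind: 1.2e-03
  k_anneal_unwind: 2.5e-03
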