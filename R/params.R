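#' Simulation parameters for the five-substep unwinding model
#'
#' `sim_params()` builds a validated parameter set for the stochastic
#' simulator; `preset_params()` returns the shipped defaults for a protein
#' variant. The kinetic fields describe one repetitive-unwinding cycle:
#' binding wait (rate `k_on * [RHA]`), activation lag (`k_act`), gradual
#' unwinding (`k_unw`, Michaelis-Menten scaled by ATP through `Km_atp`),
#' high-FRET stall (`k_stall` exit rate), instantaneous rewind, and
#' reactivation (`k_react`), with dissociation (`k_off`) competing in every
#' bound state and strand separation ending a fraction `p_sep` of completed
#' cycles. Observation-model fields set the FRET levels of duplex and unwound
#' states, the total-intensity enhancement on protein binding (PIFE), camera
#' framing, per-channel Gaussian noise and photobleaching.
#'
#' @param ... Named fields overriding the wild-type defaults shipped in
#'   `inst/extdata/preset_params.yaml`. Unknown names are an error.
#' @param variant `"wild_type"` or `"delta_dsRBD"`.
#'
#' @details
#' Fields and units:
#' * `k_on` association rate constant, M^-1 s^-1.
#' * `k_act`, `k_unw`, `k_stall`, `k_react`, `k_off`, `k_bleach` rates, s^-1
#'   (`k_unw` is the saturating-ATP unwinding rate, i.e. the Vmax of the U
#'   substep).
#' * `Km_atp` Michaelis constant of the ATP dependence of unwinding, molar.
#' * `p_sep` probability that a completed unwinding cycle ends in full strand
#'   separation (terminal), in \[0, 1\].
#' * `E_low`, `E_high` FRET efficiency of the duplex/rewound and of the fully
#'   unwound (stalled) state.
#' * `pife_gamma` total-intensity multiplier while protein is bound (>= 1).
#' * `I_total` mean total intensity of the unbound molecule; `sigma_noise`
#'   per-channel per-frame Gaussian noise SD (same units).
#' * `frame_s` frame integration time, seconds.
#' * `temp_factor` multiplicative rate scaling for the 37C condition.
#' * `gc_coef_unw`, `gc_coef_stall`, `gc_ref` exponential GC-content scaling
#'   of the unwinding and stall-exit rates:
#'   `k * exp(-coef * (gc_fraction - gc_ref))`, so AT-rich substrates unwind
#'   faster.
#' * `k_anneal_bind`, `k_anneal_unwind` effective annealing rates (s^-1) for
#'   the protein-without-ATP and protein-with-ATP annealing conditions at the
#'   variant's reference concentration.
#'
#' @return A `sim_params` object (named list).
#' @examples
#' p <- preset_params("wild_type")
#' p$k_on
#' sim_params(sigma_noise = 0)$sigma_noise
#' @export
sim_params <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  base <- preset_table()$wild_type
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    abort(paste0("Unknown simulation parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  p <- modifyList(base, over)
  validate_sim_params(p)
}

preset_table <- function() {
  path <- system.file("extdata", "preset_params.yaml", package = "unwindr")
  tab <- yaml::read_yaml(path)
  tab$delta_dsRBD <- modifyList(tab$wild_type, tab$delta_dsRBD)
  tab
}

#' @rdname sim_params
#' @export
preset_params <- function(variant = c("wild_type", "delta_dsRBD"), ...) {
  if (!is_scalar_character(variant) ||
      !variant %in% c("wild_type", "delta_dsRBD")) {
    abort("`variant` must be \"wild_type\" or \"delta_dsRBD\".")
  }
  base <- preset_table()[[variant]]
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    abort(paste0("Unknown simulation parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  validate_sim_params(modifyList(base, over))
}

validate_sim_params <- function(p) {
  rate_fields <- c("k_on", "k_act", "k_unw", "Km_atp", "k_stall", "k_react",
                   "k_off", "k_bleach", "k_anneal_bind", "k_anneal_unwind")
  for (f in c(rate_fields, "p_sep", "E_low", "E_high", "pife_gamma",
              "I_total", "sigma_noise", "frame_s", "temp_factor",
              "gc_coef_unw", "gc_coef_stall", "gc_ref")) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("Parameter `", f, "` must be a single finite number."))
    }
  }
  bad <- rate_fields[vapply(rate_fields, function(f) p[[f]] < 0, logical(1))]
  if (length(bad)) {
    abort(paste0("Rates must be >= 0; negative: ", paste(bad, collapse = ", ")))
  }
  if (p$p_sep < 0 || p$p_sep > 1) abort("`p_sep` must be in [0, 1].")
  if (!(p$E_low >= 0 && p$E_low < p$E_high && p$E_high <= 1)) {
    abort("FRET levels must satisfy 0 <= E_low < E_high <= 1.")
  }
  if (p$pife_gamma < 1) abort("`pife_gamma` must be >= 1.")
  if (p$frame_s <= 0) abort("`frame_s` must be > 0.")
  if (p$sigma_noise < 0) abort("`sigma_noise` must be >= 0.")
  if (p$temp_factor <= 0) abort("`temp_factor` must be > 0.")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Experimental condition for a simulated dataset
#'
#' One row per condition: protein variant, RHA and ATP concentrations,
#' temperature label and substrate GC fraction. Concentrations are given in
#' the bench units (nM protein, uM ATP) and stored in molar.
#'
#' @param variant `"wild_type"` or `"delta_dsRBD"` (recycled).
#' @param rha_nM RHA concentration, nM.
#' @param atp_uM ATP concentration, uM.
#' @param temperature `"RT"` (22C) or `"37C"`.
#' @param gc_fraction substrate GC content in \[0, 1\].
#' @return A tibble with columns `variant`, `rha_conc` (M), `atp_conc` (M),
#'   `temperature`, `gc_fraction` and a human-readable `condition` key.
#' @examples
#' condition(rha_nM = c(10, 20, 40, 80))
#' @export
condition <- function(variant = "wild_type", rha_nM = 40, atp_uM = 1000,
                      temperature = "RT", gc_fraction = 0.5) {
  out <- tibble(
    variant = variant,
    rha_conc = rha_nM * 1e-9,
    atp_conc = atp_uM * 1e-6,
    temperature = temperature,
    gc_fraction = gc_fraction
  )
  if (!all(out$variant %in% c("wild_type", "delta_dsRBD"))) {
    abort("`variant` must be \"wild_type\" or \"delta_dsRBD\".")
  }
  if (!all(out$temperature %in% c("RT", "37C"))) {
    abort("`temperature` must be \"RT\" or \"37C\".")
  }
  if (any(out$rha_conc < 0) || any(out$atp_conc < 0)) {
    abort("Concentrations must be >= 0.")
  }
  if (any(out$gc_fraction < 0 | out$gc_fraction > 1)) {
    abort("`gc_fraction` must be in [0, 1].")
  }
  out$condition <- sprintf("%s_rha%gnM_atp%guM_%s_gc%g",
                           out$variant, out$rha_conc * 1e9,
                           out$atp_conc * 1e6, out$temperature,
                           out$gc_fraction)
  out
}

# Condition-adjusted hazard rates actually used by the simulator.
effective_rates <- function(p, cond) {
  tf <- if (identical(cond$temperature, "37C")) p$temp_factor else 1
  gu <- exp(-p$gc_coef_unw * (cond$gc_fraction - p$gc_ref))
  gs <- exp(-p$gc_coef_stall * (cond$gc_fraction - p$gc_ref))
  atp <- cond$atp_conc
  mm <- if (atp > 0) atp / (p$Km_atp + atp) else 0
  list(
    k_bind = tf * p$k_on * cond$rha_conc,
    k_act = tf * p$k_act,
    k_u = tf * p$k_unw * gu * mm,
    k_s = tf * p$k_stall * gs,
    k_r = tf * p$k_react,
    k_off = tf * p$k_off,
    k_bleach = p$k_bleach
  )
}
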