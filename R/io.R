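#' Read and write per-molecule intensity trace tables
#'
#' Traces travel as plain CSV with mandatory header
#' `molecule_id, frame, time_s, I_D, I_A` (an optional leading `condition`
#' column is preserved), comma separator, `.` decimal, UTF-8. The round trip
#' is lossless for all fields.
#'
#' @param traces Trace tibble (see [simulate_dataset()]).
#' @param path File path; the parent directory must exist for writing.
#' @return `read_traces()` returns the validated trace tibble;
#'   `write_traces()` returns `path` invisibly.
#' @export
write_traces <- function(traces, path) {
  validate_traces(traces)
  if (!dir.exists(dirname(path))) {
    abort(paste0("Directory does not exist: ", dirname(path)))
  }
  readr::write_csv(traces, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort(paste0("No such trace file: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(trace_cols, names(out))
  if (length(missing)) {
    abort(paste0("Trace file ", path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out$molecule_id <- as.integer(out$molecule_id)
  out$frame <- as.integer(out$frame)
  validate_traces(out, arg = basename(path))
  out
}

#' @rdname write_traces
#' @param manifest Manifest tibble from [simulate_dataset()].
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", digits = NA,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_manifest <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

config_keys <- c("variant", "rha_nM", "atp_uM", "temperature",
                 "gc_fraction", "n_molecules", "duration_s", "obs_start_s",
                 "seed", "out_dir", "thresholds", "params", "run_annealing",
                 "annealing_snapshots", "annealing_n")
threshold_keys <- c("e_low_max", "e_high_min", "min_ramp_frames", "median_k",
                    "window", "alpha", "total_floor")

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or YAML file) describing one
#' end-to-end run: simulation condition grid (`rha_nM` and `atp_uM` may be
#' vectors, in bench units nM/uM), dataset size, seed, optional parameter
#' and threshold overrides, and optional annealing stage. Unknown keys are
#' rejected before any stage runs.
#'
#' @param config Named list, or path to a YAML file holding one.
#' @return The validated config (list) with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a named list or YAML path.")
  unknown <- setdiff(names(config), config_keys)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults <- list(variant = "wild_type", rha_nM = 40, atp_uM = 1000,
                   temperature = "RT", gc_fraction = 0.5, n_molecules = 50,
                   duration_s = 120, obs_start_s = 0, seed = 1,
                   out_dir = NULL, thresholds = list(), params = list(),
                   run_annealing = FALSE,
                   annealing_snapshots = seq(0, 600, by = 60),
                   annealing_n = 1000)
  config <- modifyList(defaults, config)
  bad_thr <- setdiff(names(config$thresholds), threshold_keys)
  if (length(bad_thr)) {
    abort(paste0("Unknown threshold key(s): ",
                 paste(bad_thr, collapse = ", ")))
  }
  if (config$n_molecules < 1) abort("`n_molecules` must be >= 1.")
  if (config$duration_s <= 0) abort("`duration_s` must be > 0.")
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    abort("`seed` must be a single integer.")
  }
  config
}

#' Analyze intensity traces end to end
#'
#' Composition of the analysis chain on an in-memory trace table:
#' FRET/total-intensity computation, binding/dissociation step detection,
#' substep idealization, dwell extraction, per-event summaries and substep
#' rate estimation (grouped by condition when present).
#'
#' @param traces Trace tibble (simulated or read with [read_traces()]).
#' @param thresholds Named list overriding any of `e_low_max`, `e_high_min`,
#'   `min_ramp_frames`, `median_k`, `window`, `alpha`, `total_floor`.
#' @param t0 Reagent-addition time for the B dwell origin.
#' @return List of class `trace_analysis` with tibbles `fret`, `steps`,
#'   `segments`, `dwells`, `events`, `rates`, `off_rate`.
#' @export
analyze_traces <- function(traces, thresholds = list(), t0 = 0) {
  thr <- modifyList(list(e_low_max = 0.35, e_high_min = 0.65,
                         min_ramp_frames = 2L, median_k = 3L,
                         window = 10L, alpha = 0.01, total_floor = NULL),
                    thresholds)
  fret <- compute_fret(traces, total_floor = thr$total_floor)
  steps <- detect_intensity_steps(fret, window = thr$window,
                                  alpha = thr$alpha)
  segments <- segment_substeps(fret, steps, e_low_max = thr$e_low_max,
                               e_high_min = thr$e_high_min,
                               min_ramp_frames = thr$min_ramp_frames,
                               median_k = thr$median_k)
  dwells <- extract_dwells(segments, t0 = t0)
  events <- if (nrow(segments)) event_summary(segments) else
    tibble(molecule_id = integer(0), event = integer(0),
           total_bound_s = numeric(0), bound_censored = logical(0),
           n_cycles = integer(0), terminal_class = character(0))
  grp <- intersect("condition", names(dwells))
  rates <- if (nrow(dwells)) {
    estimate_rate(dwells, all_of(grp))
  } else tibble(substep = character(0), rate = numeric(0),
                sem = numeric(0), n = integer(0), n_censored = integer(0))
  off <- if (nrow(events) && any(!events$bound_censored)) {
    ok <- events |>
      summarise(any_unc = any(!.data$bound_censored), .by = all_of(grp))
    keep <- events
    if (length(grp)) {
      keep <- semi_join(events, ok[ok$any_unc, , drop = FALSE], by = grp)
    }
    estimate_off_rate(keep, all_of(grp))
  } else NULL
  structure(list(fret = fret, steps = steps, segments = segments,
                 dwells = dwells, events = events, rates = rates,
                 off_rate = off),
            class = "trace_analysis")
}

#' Run the simulate-process-segment-fit pipeline from a configuration
#'
#' Simulates the condition grid described by the config (crossing the
#' `rha_nM` and `atp_uM` vectors), runs the full analysis chain, and --
#' when the grid spans several ATP or protein concentrations -- fits the
#' Michaelis-Menten ATP dependence of unwinding and the zero-intercept
#' association-constant line to the binding rates. Optionally simulates and
#' fits annealing time courses. Fully deterministic for a given config.
#'
#' @param config See [validate_config()].
#' @return List of class `unwind_report`: package version, config hash,
#'   seed, the manifest, per-condition `rates` and `off_rate` tables, event
#'   summaries (`cycles`), and `fits` (Michaelis-Menten / association /
#'   annealing, when computed). If `out_dir` is set, traces, dwells, rates
#'   and the JSON report are written there.
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(n_molecules = 5, duration_s = 60, seed = 1))
#' rep$rates
#' }
#' @export
run_pipeline <- function(config = list()) {
  config <- validate_config(config)
  params <- do.call(sim_params, modifyList(
    as.list(unclass(preset_params(config$variant))), config$params))
  conds <- condition(variant = config$variant,
                     rha_nM = rep(config$rha_nM,
                                  each = length(config$atp_uM)),
                     atp_uM = rep(config$atp_uM,
                                  times = length(config$rha_nM)),
                     temperature = config$temperature,
                     gc_fraction = config$gc_fraction)
  ds <- simulate_dataset(params, conds, n_molecules = config$n_molecules,
                         duration_s = config$duration_s,
                         seed = config$seed,
                         obs_start_s = config$obs_start_s)
  an <- analyze_traces(ds$traces, thresholds = config$thresholds)
  rates <- left_join(an$rates,
                     ds$manifest |>
                       select("condition", "rha_conc", "atp_conc"),
                     by = intersect("condition", names(an$rates)))
  fits <- list()
  if (length(unique(conds$atp_conc)) >= 3L) {
    u <- rates |> filter(.data$substep == "U")
    if (nrow(u) >= 3L) {
      fits$michaelis_menten <- fit_michaelis_menten(
        u, conc_col = "atp_conc", rate_col = "rate", sem_col = "sem")
    }
  }
  if (length(unique(conds$rha_conc)) >= 2L) {
    b <- rates |> filter(.data$substep == "B")
    if (nrow(b) >= 2L) {
      fits$association <- fit_association_constant(
        b, conc_col = "rha_conc", rate_col = "rate", sem_col = "sem")
    }
  }
  if (isTRUE(config$run_annealing)) {
    cond1 <- conds[1L, ]
    tc_atp <- simulate_annealing_field(
      params, cond1, config$annealing_n, config$annealing_snapshots,
      include_atp = TRUE, seed = config$seed + 1L)
    tc_no <- simulate_annealing_field(
      params, cond1, config$annealing_n, config$annealing_snapshots,
      include_atp = FALSE, seed = config$seed + 2L)
    fit_atp <- estimate_annealing_rate(annealing_fraction_curve(tc_atp))
    fit_no <- estimate_annealing_rate(annealing_fraction_curve(tc_no))
    fits$annealing <- list(
      rate_with_atp = fit_atp$rate, se_with_atp = fit_atp$se,
      rate_without_atp = fit_no$rate, se_without_atp = fit_no$se,
      enhancement = as.list(enhancement_factor(fit_atp, fit_no)))
  }
  cycles <- an$events |>
    summarise(n_events = n(),
              median_cycles = stats::median(.data$n_cycles),
              .by = any_of("condition"))
  report <- structure(list(
    package = "unwindr",
    version = as.character(utils::packageVersion("unwindr")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    manifest = ds$manifest,
    rates = rates,
    off_rate = an$off_rate,
    cycles = cycles,
    fits = fits
  ), class = "unwind_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_traces(ds$traces, file.path(config$out_dir, "traces.csv"))
    write_manifest(ds$manifest, file.path(config$out_dir, "manifest.json"))
    readr::write_tsv(an$dwells, file.path(config$out_dir, "dwells.tsv"))
    readr::write_tsv(rates, file.path(config$out_dir, "rates.tsv"))
    jsonlite::write_json(report_to_json(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_json <- function(report) {
  out <- unclass(report)
  out$manifest <- as.data.frame(report$manifest)
  out$rates <- as.data.frame(report$rates)
  if (!is.null(out$off_rate)) out$off_rate <- as.data.frame(out$off_rate)
  out$cycles <- as.data.frame(report$cycles)
  out$fits <- lapply(report$fits, function(f) {
    if (inherits(f, c("mm_fit", "assoc_fit"))) as.list(glance(f)) else f
  })
  out
}

#' @export
print.unwind_report <- function(x, ...) {
  cat("<unwind_report> unwindr", x$version, "| seed", x$seed, "\n")
  cat("Conditions:", nrow(x$manifest), "| events:",
      sum(x$cycles$n_events), "\n")
  print(x$rates)
  if (!is.null(x$fits$michaelis_menten)) {
    g <- x$fits$michaelis_menten
    cat(sprintf("Michaelis-Menten: Vmax = %.3g /s, Km = %.3g uM (%s)\n",
                g$vmax, g$km * 1e6,
                if (g$converged) "converged" else "NOT converged"))
  }
  if (!is.null(x$fits$association)) {
    g <- x$fits$association
    cat(sprintf("Association constant: %.3g x 1e6 /M/s\n", g$slope / 1e6))
  }
  invisible(x)
}
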