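rexp1 <- function(k) if (k > 0) stats::rexp(1L, k) else Inf

# Draw one continuous-time state path under the five-substep cycle.
# Labels: unbound, A, U, S, R plus terminal fillers separated / dissociated /
# bleached. Uses the current RNG stream. Returns a tibble of contiguous
# segments with, for U segments, the full drawn unwinding duration (ramp_T,
# the time the FRET ramp would need to reach E_high) and an exit code per
# segment ("transition" = the state's own kinetic transition fired; anything
# else censors the dwell).
sample_state_path <- function(p, cond, duration_s) {
  eff <- effective_rates(p, cond)
  lab <- character(0); t0 <- numeric(0); t1 <- numeric(0)
  ramp <- numeric(0); exit <- character(0)
  add <- function(label, a, b, rampT = NA_real_, ex = "transition") {
    lab[[length(lab) + 1L]] <<- label
    t0[[length(t0) + 1L]] <<- a
    t1[[length(t1) + 1L]] <<- b
    ramp[[length(ramp) + 1L]] <<- rampT
    exit[[length(exit) + 1L]] <<- ex
  }
  t_bleach <- rexp1(eff$k_bleach)
  terminal <- "trace_end"
  n_cycles <- 0L
  t <- 0

  t_bind <- rexp1(eff$k_bind)
  if (t_bleach <= min(t_bind, duration_s)) {
    add("unbound", 0, t_bleach, ex = "bleach")
    add("bleached", t_bleach, duration_s, ex = "terminal")
    terminal <- "bleached"
  } else if (t_bind >= duration_s) {
    add("unbound", 0, duration_s, ex = "end")
  } else {
    add("unbound", 0, t_bind)
    t <- t_bind
    state <- "A"
    repeat {
      k_state <- switch(state, A = eff$k_act, U = eff$k_u,
                        S = eff$k_s, R = eff$k_r)
      T_full <- rexp1(k_state)
      t_nat <- t + T_full
      t_off <- t + rexp1(eff$k_off)
      t_stop <- min(t_nat, t_off, t_bleach, duration_s)
      rampT <- if (state == "U") T_full else NA_real_
      ex <- if (t_stop == t_nat) "transition"
            else if (t_stop == t_off) "off"
            else if (t_stop == t_bleach) "bleach" else "end"
      add(state, t, t_stop, rampT, ex)
      if (ex == "bleach") {
        add("bleached", t_bleach, duration_s, ex = "terminal")
        terminal <- "bleached"
        break
      }
      if (ex == "end") break
      if (ex == "off") {
        add("dissociated", t_off, duration_s, ex = "terminal")
        terminal <- "dissociated"
        break
      }
      t <- t_nat
      if (state == "A" || state == "R") {
        state <- "U"
      } else if (state == "U") {
        state <- "S"
        n_cycles <- n_cycles + 1L
      } else { # leaving S: instantaneous rewind, maybe full separation
        if (stats::runif(1L) < p$p_sep) {
          add("separated", t, duration_s, ex = "terminal")
          terminal <- "separated"
          break
        }
        state <- "R"
      }
      if (t >= duration_s) break
    }
  }
  out <- tibble(label = lab, t_start = t0, t_end = t1,
                ramp_T = ramp, exit = exit)
  out <- out[out$t_end > out$t_start | out$label %in%
               c("separated", "dissociated", "bleached"), , drop = FALSE]
  attr(out, "terminal") <- terminal
  attr(out, "n_cycles") <- n_cycles
  out
}

# Render per-frame donor/acceptor intensities from a state path (absolute
# time); frames cover [obs_start, obs_start + n_frames * frame_s), each frame
# reporting the state at its midpoint. FRET ramps linearly across the U dwell
# and drops instantaneously on rewinding; totals carry the PIFE factor while
# bound; separated/bleached frames are background + noise only.
render_trace <- function(path, p, n_frames, obs_start = 0) {
  tm <- obs_start + (seq_len(n_frames) - 0.5) * p$frame_s
  idx <- findInterval(tm, path$t_start)
  idx[idx < 1L] <- 1L
  lab <- path$label[idx]
  E <- rep(p$E_low, n_frames)
  E[lab == "S"] <- p$E_high
  u <- which(lab == "U")
  if (length(u)) {
    frac <- (tm[u] - path$t_start[idx[u]]) / path$ramp_T[idx[u]]
    E[u] <- p$E_low + (p$E_high - p$E_low) * pmin(1, frac)
  }
  total <- rep(p$I_total, n_frames)
  total[lab %in% c("A", "U", "S", "R")] <- p$pife_gamma * p$I_total
  dark <- lab %in% c("bleached", "separated")
  total[dark] <- 0
  E[dark] <- 0
  I_A <- E * total
  I_D <- (1 - E) * total
  if (p$sigma_noise > 0) {
    I_D <- I_D + stats::rnorm(n_frames, 0, p$sigma_noise)
    I_A <- I_A + stats::rnorm(n_frames, 0, p$sigma_noise)
  }
  tibble(frame = seq_len(n_frames) - 1L,
         time_s = (seq_len(n_frames) - 1L) * p$frame_s,
         I_D = I_D, I_A = I_A)
}

shift_clip_path <- function(path, offset, duration_s) {
  out <- path
  out$t_start <- pmax(out$t_start - offset, 0)
  out$t_end <- pmin(out$t_end - offset, duration_s)
  keep <- out$t_end > out$t_start |
    out$label %in% c("separated", "dissociated", "bleached")
  keep <- keep & out$t_end >= 0 & out$t_start <= duration_s
  res <- out[keep, , drop = FALSE]
  attr(res, "terminal") <- attr(path, "terminal")
  attr(res, "n_cycles") <- attr(path, "n_cycles")
  res
}

#' Simulate one ground-truthed smFRET trace
#'
#' Draws a continuous-time state path of the five-substep repetitive
#' unwinding cycle (Gillespie-style competing exponential clocks) and renders
#' it as a two-channel intensity trace at the camera frame rate. Dissociation
#' competes with every bound-state dwell, photobleaching competes globally,
#' and each completed unwinding/stall cycle ends in full strand separation
#' with probability `p_sep` (terminal: both dyes leave the surface with the
#' unwound strand, so both channels drop to background).
#'
#' @param params A [sim_params] object.
#' @param cond One-row condition tibble from [condition()].
#' @param duration_s Observed trace length, seconds (> 0).
#' @param seed Integer seed; identical seed, params and condition give an
#'   identical trace. `NULL` uses the current RNG stream.
#' @param obs_start_s Reaction time at which observation starts (the reaction
#'   runs from time 0; frames cover `[obs_start_s, obs_start_s + duration_s)`
#'   and returned times are relative to the first frame). Non-zero values
#'   emulate snapshots of an already-running reaction.
#' @param molecule_id Integer id stored in the outputs.
#' @return A list of class `sim_trace` with `$trace` (tibble: `molecule_id`,
#'   `frame` (0-based), `time_s`, `I_D`, `I_A`) and `$path` (tibble of ground
#'   truth segments: `label`, `t_start`, `t_end`, `censored`), plus the
#'   terminal class and cycle count as attributes of `$path`.
#' @examples
#' p <- sim_params(sigma_noise = 0)
#' tr <- simulate_trace(p, condition(), duration_s = 60, seed = 1)
#' head(tr$trace)
#' @export
simulate_trace <- function(params, cond = condition(), duration_s,
                           seed = NULL, obs_start_s = 0, molecule_id = 0L) {
  params <- validate_sim_params(params)
  stopifnot(is.data.frame(cond), nrow(cond) == 1L)
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be a single positive number.")
  }
  if (obs_start_s < 0) abort("`obs_start_s` must be >= 0.")
  run <- function() {
    n_frames <- floor(duration_s / params$frame_s + 1e-9)
    total_dur <- obs_start_s + n_frames * params$frame_s
    path <- sample_state_path(params, as.list(cond), total_dur)
    trace <- render_trace(path, params, n_frames, obs_start_s)
    list(path = path, trace = trace)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  path <- shift_clip_path(res$path, obs_start_s,
                          nrow(res$trace) * params$frame_s)
  path$censored <- path$exit != "transition"
  path <- tibble(molecule_id = as.integer(molecule_id),
                 as_tibble(path)[c("label", "t_start", "t_end",
                                   "ramp_T", "exit", "censored")])
  attr(path, "terminal") <- attr(res$path, "terminal")
  attr(path, "n_cycles") <- attr(res$path, "n_cycles")
  trace <- tibble(molecule_id = as.integer(molecule_id), res$trace)
  structure(list(trace = trace, path = path), class = "sim_trace")
}

#' Simulate a ground-truthed multi-condition trace dataset
#'
#' Batch wrapper over [simulate_trace()]: for every condition row,
#' `n_molecules` traces are drawn with per-molecule child seeds derived
#' deterministically from `seed`, so a run is exactly reproducible.
#'
#' @inheritParams simulate_trace
#' @param conditions Condition tibble from [condition()] (>= 1 row).
#' @param n_molecules Traces per condition (>= 1).
#' @param seed Integer root seed.
#' @return A list of class `sim_dataset` with tibbles `$traces` (all frames,
#'   keyed by `condition` and 0-based `molecule_id`), `$paths` (ground-truth
#'   segments with per-trace `terminal` and `n_cycles`), and `$manifest`
#'   (one row per condition: condition fields, `n_molecules`, `seed`, and a
#'   hash of the generating parameters).
#' @examples
#' ds <- simulate_dataset(sim_params(), condition(), n_molecules = 2,
#'                        duration_s = 20, seed = 1)
#' ds$manifest
#' @export
simulate_dataset <- function(params, conditions, n_molecules, duration_s,
                             seed, obs_start_s = 0) {
  params <- validate_sim_params(params)
  if (!is.data.frame(conditions) || nrow(conditions) < 1L) {
    abort("`conditions` must be a condition tibble with at least one row.")
  }
  if (!is.numeric(n_molecules) || n_molecules < 1) {
    abort("`n_molecules` must be >= 1.")
  }
  n_molecules <- as.integer(n_molecules)
  traces <- vector("list", nrow(conditions) * n_molecules)
  paths <- vector("list", length(traces))
  k <- 0L
  for (i in seq_len(nrow(conditions))) {
    ci <- conditions[i, ]
    for (j in seq_len(n_molecules)) {
      child <- as.integer((abs(seed) * 7 + (i - 1) * 1000003 + j * 101) %%
                            2147483629)
      sim <- simulate_trace(params, ci, duration_s, seed = child,
                            obs_start_s = obs_start_s,
                            molecule_id = j - 1L)
      k <- k + 1L
      traces[[k]] <- tibble(condition = ci$condition, sim$trace)
      pth <- tibble(condition = ci$condition, sim$path,
                    terminal = attr(sim$path, "terminal"),
                    n_cycles = attr(sim$path, "n_cycles"))
      paths[[k]] <- pth
    }
  }
  manifest <- conditions
  manifest$n_molecules <- n_molecules
  manifest$duration_s <- duration_s
  manifest$obs_start_s <- obs_start_s
  manifest$seed <- seed
  manifest$params_hash <- rlang::hash(unclass(params))
  structure(list(traces = list_rbind(traces), paths = list_rbind(paths),
                 manifest = manifest),
            class = "sim_dataset")
}

#' Simulate an annealing field-of-view time course
#'
#' Emulates the surface-snapshot annealing assay: each of `n_molecules`
#' immobilized duplexes acquires a complementary high-FRET strand at an
#' exponential time whose rate depends on the condition -- 0 without protein,
#' the preset's binding-induced rate without ATP, or its unwinding-induced
#' rate with ATP. Counts of annealed (high-FRET) molecules are reported at
#' each snapshot time.
#'
#' @inheritParams simulate_trace
#' @param n_molecules Number of molecules in the field (>= 1).
#' @param snapshot_times Strictly increasing times (s), at least 2.
#' @param include_atp Logical; with ATP the unwinding-induced rate applies.
#' @return Tibble of class `annealing_timecourse` with `time_s`, `annealed`,
#'   `total`; the generating rate and per-molecule annealing times are kept
#'   as attributes `k_true` and `anneal_times`.
#' @examples
#' tc <- simulate_annealing_field(sim_params(), condition(), 500,
#'                                snapshot_times = c(0, 60, 120, 300),
#'                                include_atp = TRUE, seed = 1)
#' tc
#' @export
simulate_annealing_field <- function(params, cond = condition(), n_molecules,
                                     snapshot_times, include_atp = TRUE,
                                     seed = NULL) {
  params <- validate_sim_params(params)
  stopifnot(is.data.frame(cond), nrow(cond) == 1L)
  if (!is.numeric(n_molecules) || n_molecules < 1) {
    abort("`n_molecules` must be >= 1.")
  }
  if (length(snapshot_times) < 2L || any(diff(snapshot_times) <= 0)) {
    abort("`snapshot_times` must be >= 2 strictly increasing times.")
  }
  k <- if (cond$rha_conc <= 0) 0
       else if (include_atp && cond$atp_conc > 0) params$k_anneal_unwind
       else params$k_anneal_bind
  draw <- function() {
    if (k > 0) stats::rexp(as.integer(n_molecules), k)
    else rep(Inf, as.integer(n_molecules))
  }
  times <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- tibble(
    time_s = as.numeric(snapshot_times),
    annealed = vapply(snapshot_times,
                      function(t) sum(times <= t), integer(1)),
    total = as.integer(n_molecules)
  )
  attr(out, "k_true") <- k
  attr(out, "anneal_times") <- times
  class(out) <- c("annealing_timecourse", class(out))
  out
}
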