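# Idealization of bound intervals into A/U/S/R substeps.
#
# Within one binding event the FRET trajectory is a two-level system with
# gradual rises: flat low-band dwells (A first, R afterwards), a monotone
# ramp from the low to the high band (U), flat high-band dwells (S) and an
# effectively instantaneous drop closing each cycle. Stall runs are located
# as runs of median-filtered FRET above the high-band floor; the U boundaries
# are then refined by fitting a line through the mid-band ramp frames and
# intersecting it with the event's low and high FRET levels, which localizes
# the boundaries to well under a frame on clean data and stays unbiased under
# noise.

# Refine the two unwinding boundaries by least squares against the raw
# FRET under the piecewise model low plateau -> linear ramp -> high
# plateau, searching a local grid around the initial estimates (which are
# kept as candidates, so exact noiseless estimates are never degraded).
refine_ramp <- function(tm, E, low_ref, high_ref, t0_init, t1_init,
                        lo_bound, hi_bound, frame_s) {
  use <- tm >= max(lo_bound, t0_init - 15 * frame_s) &
    tm <= min(hi_bound, t1_init + 15 * frame_s)
  if (sum(use) < 4L) return(c(t0_init, t1_init))
  tmu <- tm[use]; Eu <- E[use]
  g0 <- seq(t0_init - 5 * frame_s, t0_init + 5 * frame_s, by = frame_s / 2)
  g1 <- seq(t1_init - 5 * frame_s, t1_init + 5 * frame_s, by = frame_s / 2)
  g0 <- pmin(pmax(g0, lo_bound), hi_bound)
  g1 <- pmin(pmax(g1, lo_bound), hi_bound)
  cand <- rbind(expand.grid(t0 = unique(g0), t1 = unique(g1)),
                data.frame(t0 = t0_init, t1 = t1_init))
  cand <- cand[cand$t1 >= cand$t0, , drop = FALSE]
  dE <- high_ref - low_ref
  sse <- vapply(seq_len(nrow(cand)), function(i) {
    t0 <- cand$t0[i]; t1 <- cand$t1[i]
    pred <- ifelse(tmu <= t0, low_ref,
                   ifelse(tmu >= t1, high_ref,
                          low_ref + dE * (tmu - t0) / max(t1 - t0, 1e-9)))
    sum((Eu - pred)^2)
  }, numeric(1))
  best <- which.min(sse)
  c(cand$t0[best], cand$t1[best])
}

seg_event <- function(times, E, frame_s, e_low_max, e_high_min,
                      min_ramp_frames, median_k, t_event_end,
                      terminal_class) {
  m <- length(E)
  t_ev0 <- times[1L]
  ef <- if (m >= median_k) {
    stats::runmed(E, median_k, endrule = "median")
  } else E
  sdE <- if (m >= 3L) stats::mad(diff(E)) / sqrt(2) else 0
  slack <- max(0.02, 2 * sdE)
  lowv <- ef[ef <= e_low_max]
  low_ref <- if (length(lowv)) stats::median(lowv) else min(ef)
  # stall level from the top of the high band only: slow unwinding ramps
  # also populate the band and would drag a plain median down
  highv <- ef[ef >= e_high_min]
  high_ref <- if (length(highv)) {
    top <- stats::quantile(highv, 0.95, names = FALSE)
    stats::median(highv[highv >= top - max(0.05, 2 * slack)])
  } else NA_real_

  labs <- character(0); a <- numeric(0); b <- numeric(0)
  push <- function(label, ta, tb) {
    labs[[length(labs) + 1L]] <<- label
    a[[length(a) + 1L]] <<- ta
    b[[length(b) + 1L]] <<- tb
  }

  # U boundaries from a line through the mid-band ramp frames
  ramp_cross <- function(fit_idx, fallback_start, fallback_end) {
    if (length(fit_idx) >= max(2L, min_ramp_frames)) {
      tm <- times[fit_idx] + frame_s / 2
      cf <- stats::coef(stats::lm(ef[fit_idx] ~ tm))
      if (is.finite(cf[2]) && cf[2] > 0) {
        t_lo <- (low_ref - cf[1]) / cf[2]
        t_hi <- if (is.finite(high_ref)) (high_ref - cf[1]) / cf[2] else
          fallback_end
        return(c(t_lo, t_hi))
      }
    }
    c(fallback_start, fallback_end)
  }

  # a cycle (unwinding ramp + stall) shows up as a run of filtered FRET
  # above the mid band; the stall itself as frames near the high level.
  # If no frame ever reaches the high band, the event holds no stall at
  # all -- any mid-band run is an (interrupted) unwinding ramp.
  e_mid <- (e_low_max + e_high_min) / 2
  r <- rle(ef >= e_mid)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  s_runs <- which(r$values)
  # Merge runs that noise split. A genuine rewind (a) only happens after
  # the stall level was reached and (b) returns the FRET to the low
  # level. So two runs stay separate cycles when the gap's filtered FRET
  # touches the low band, or when the earlier run reached the high band
  # and even a single raw frame in a short gap touched low (a sub-frame
  # rewind the median filter smoothed away); anything else is one
  # excursion.
  if (length(s_runs) > 1L) {
    starts <- run_start[s_runs]; ends <- run_end[s_runs]
    ms <- starts[1]; me <- ends[1]
    merged <- list()
    for (k in seq_along(s_runs)[-1]) {
      gap <- (me + 1L):(starts[k] - 1L)
      reached_high <- any(ef[ms:me] >= e_high_min)
      split_here <- any(ef[gap] <= low_ref + slack) ||
        (reached_high && (length(gap) > 2L ||
                            any(E[gap] <= low_ref + slack)))
      if (split_here) {
        merged[[length(merged) + 1L]] <- c(ms, me)
        ms <- starts[k]; me <- ends[k]
      } else {
        me <- ends[k]
      }
    }
    merged[[length(merged) + 1L]] <- c(ms, me)
    run_start <- vapply(merged, `[`, integer(1), 1L)
    run_end <- vapply(merged, `[`, integer(1), 2L)
    s_runs <- seq_along(merged)
  }
  prev_end_t <- t_ev0
  gap_lo <- 1L
  first_low_label <- "A"

  for (sr in s_runs) {
    s0 <- run_start[sr]; s1 <- run_end[sr]
    gap_idx <- if (gap_lo <= s0 - 1L) gap_lo:(s0 - 1L) else integer(0)
    low_idx <- gap_idx[ef[gap_idx] <= low_ref + slack]
    low_exit <- if (length(low_idx)) max(low_idx) else gap_lo - 1L
    ramp_idx <- gap_idx[gap_idx > low_exit]
    # first run frame at the stall level; earlier run frames are ramp tail
    stall_entry <- if (is.finite(high_ref)) {
      cand <- (s0:s1)[ef[s0:s1] >= high_ref - slack]
      if (length(cand)) cand[1] else NA_integer_
    } else NA_integer_
    ext <- if (is.na(stall_entry)) s0:s1 else
      if (stall_entry > s0) s0:(stall_entry - 1L) else integer(0)
    fit_idx <- c(ramp_idx, ext)
    fit_idx <- fit_idx[ef[fit_idx] > low_ref + slack &
                         (!is.finite(high_ref) |
                            ef[fit_idx] < high_ref - slack)]
    run_end_t <- if (s1 < m) times[s1 + 1L] else t_event_end
    fb_start <- if (length(ramp_idx)) times[min(ramp_idx)] else times[s0]
    fb_end <- if (!is.na(stall_entry)) times[stall_entry] else run_end_t
    line_cf <- NULL
    if (length(fit_idx) >= max(2L, min_ramp_frames)) {
      tmf <- times[fit_idx] + frame_s / 2
      cf <- stats::coef(stats::lm(ef[fit_idx] ~ tmf))
      # a usable ramp must rise appreciably per frame, not just by
      # floating-point noise
      if (is.finite(cf[2]) && cf[2] * frame_s > slack / 50) {
        line_cf <- unname(cf)
      }
    }
    uc <- if (!is.null(line_cf)) {
      c((low_ref - line_cf[1]) / line_cf[2],
        if (is.finite(high_ref)) (high_ref - line_cf[1]) / line_cf[2] else
          fb_end)
    } else c(fb_start, fb_end)
    t_u0 <- min(max(uc[1], prev_end_t), times[s0] + frame_s)
    # decide whether a run that touches the event end carries a stall at
    # all, or is an unwinding ramp censored mid-rise
    ramp_censored <- FALSE
    if (s1 == m) {
      if (!is.finite(high_ref)) {
        ramp_censored <- TRUE
      } else if (is.na(stall_entry)) {
        ramp_censored <- uc[2] > run_end_t
      } else if (!is.null(line_cf)) {
        # a stall is declared only when capping the ramp at the stall
        # level explains the run strictly better than letting the line
        # continue to rise
        idx_all <- unique(c(fit_idx, s0:s1))
        tma <- times[idx_all] + frame_s / 2
        line_pred <- line_cf[1] + line_cf[2] * tma
        sse_line <- sum((ef[idx_all] - line_pred)^2)
        sse_cap <- sum((ef[idx_all] - pmin(line_pred, high_ref))^2)
        ramp_censored <- sse_line <= sse_cap
      }
    } else if (!is.finite(high_ref)) {
      # interior excursion in an event with no stall level anywhere:
      # an unwinding attempt that fell back without a visible stall
      ramp_censored <- TRUE
    }
    if (ramp_censored) {
      push(first_low_label, prev_end_t, t_u0)
      push("U", t_u0, run_end_t)
      prev_end_t <- run_end_t
      gap_lo <- s1 + 1L
      first_low_label <- "R"
      next
    }
    t_u1 <- min(max(uc[2], t_u0), run_end_t)
    if (sdE > 0.01) {
      rc <- refine_ramp(times + frame_s / 2, E, low_ref, high_ref,
                        t_u0, t_u1, prev_end_t, run_end_t, frame_s)
      t_u0 <- rc[1]; t_u1 <- max(rc[2], rc[1])
    }
    push(first_low_label, prev_end_t, t_u0)
    push("U", t_u0, t_u1)
    push("S", t_u1, run_end_t)
    prev_end_t <- run_end_t
    gap_lo <- s1 + 1L
    first_low_label <- "R"
  }

  # trailing region after the last stall (or the whole event if none)
  if (gap_lo <= m) {
    tg <- gap_lo:m
    low_idx <- tg[ef[tg] <= low_ref + slack]
    low_exit <- if (length(low_idx)) max(low_idx) else gap_lo - 1L
    ramp_t <- tg[tg > low_exit]
    rising <- length(ramp_t) > 0L && ef[m] > low_ref + slack
    if (rising) {
      fit_idx <- ramp_t[ef[ramp_t] > low_ref + slack]
      t_u0 <- if (length(fit_idx) >= 2L) {
        tm <- times[fit_idx] + frame_s / 2
        cf <- stats::coef(stats::lm(ef[fit_idx] ~ tm))
        if (is.finite(cf[2]) && cf[2] * frame_s > slack / 50) {
          (low_ref - cf[1]) / cf[2]
        } else times[min(ramp_t)]
      } else times[min(ramp_t)]
      t_u0 <- max(t_u0, prev_end_t)
      t_u0 <- min(max(t_u0, prev_end_t), t_event_end)
      push(first_low_label, prev_end_t, t_u0)
      push("U", t_u0, t_event_end)
    } else {
      push(first_low_label, prev_end_t, t_event_end)
    }
  } else if (prev_end_t < t_event_end) {
    # event ends inside the final stall drop; nothing left to label
  }

  seg <- tibble(label = labs, t_start = a, t_end = b)
  # a trailing sub-frame stall without an observed signal-loss drop is not
  # evidence of stall entry; fold it back into a censored unwinding ramp
  n_seg <- nrow(seg)
  if (n_seg >= 2L && !identical(terminal_class, "separated_or_bleached") &&
      seg$label[n_seg] == "S" &&
      seg$t_end[n_seg] - seg$t_start[n_seg] < frame_s &&
      seg$label[n_seg - 1L] == "U") {
    seg$t_end[n_seg - 1L] <- seg$t_end[n_seg]
    seg <- seg[-n_seg, , drop = FALSE]
  }
  # enforce monotone, non-overlapping boundaries
  seg$t_start <- cummax(seg$t_start)
  seg$t_end <- pmax(seg$t_end, seg$t_start)
  seg$t_end <- rev(cummin(rev(pmin(seg$t_end, t_event_end))))
  seg$t_start <- pmin(seg$t_start, seg$t_end)
  drop <- seg$t_end - seg$t_start <= 0 & !seg$label %in% c("U", "S")
  seg <- seg[!drop, , drop = FALSE]
  seg$censored <- FALSE
  if (nrow(seg)) {
    last <- nrow(seg)
    seg$censored[last] <-
      !(seg$label[last] == "S" &&
          identical(terminal_class, "separated_or_bleached"))
  }
  seg
}

#' Idealize bound intervals into the B/A/U/S/R substep grammar
#'
#' Uses the binding/dissociation step events to delimit bound intervals,
#' then classifies frames within each interval: the first low-FRET dwell is
#' activation (A), a sustained rise from the low band into the high band is
#' unwinding (U), high-band dwells are stalls (S), and low-FRET dwells after
#' a drop are reactivation (R). The rapid rewinding drop is assigned zero
#' duration; its frames attach to the following R. The pre-binding wait (B)
#' is not a segment -- it is recovered by [extract_dwells()] as the time from
#' acquisition start (or a configurable reagent-addition offset) to the
#' binding up-step.
#'
#' @param fret A [compute_fret()] result.
#' @param steps A [detect_intensity_steps()] result for the same traces.
#' @param e_low_max Ceiling of the low-FRET band used to detect dwells.
#' @param e_high_min Floor of the high-FRET band used to detect stalls.
#' @param min_ramp_frames Minimum mid-band frames for line-fit refinement of
#'   unwinding boundaries.
#' @param median_k Median filter width (frames, odd) applied to FRET for
#'   segmentation only; dwell arithmetic never uses filtered values.
#' @return Tibble of class `substep_annotation`: `molecule_id`
#'   (+`condition`), `event` (binding-event index), `label` (`A`,`U`,`S`,`R`),
#'   `t_start`, `t_end` (s), `censored`, plus per-event metadata `t_bind`,
#'   `t_unbind`, `terminal_class` (`dissociated`, `separated_or_bleached`,
#'   `trace_end`) and `multi_binder`. Zero rows when no bound interval exists.
#' @export
segment_substeps <- function(fret, steps, e_low_max = 0.35,
                             e_high_min = 0.65, min_ramp_frames = 2L,
                             median_k = 3L) {
  if (e_low_max >= e_high_min) {
    abort("Low-FRET band must lie strictly below the high-FRET band.")
  }
  if (median_k %% 2L == 0L) median_k <- median_k + 1L
  keys <- intersect(c("condition", "molecule_id"), names(fret))
  frame_s <- attr(steps, "frame_s") %||% infer_frame_s(fret)

  one <- function(d, st) {
    d <- d[d$valid & is.finite(d$E), , drop = FALSE]
    empty <- tibble(event = integer(0), label = character(0),
                    t_start = numeric(0), t_end = numeric(0),
                    censored = logical(0), t_bind = numeric(0),
                    t_unbind = numeric(0), terminal_class = character(0),
                    multi_binder = logical(0))
    if (nrow(d) == 0L || nrow(st) == 0L) return(empty)
    st <- st[order(st$frame), , drop = FALSE]
    events <- list()
    open_frame <- NA_integer_
    multi <- FALSE
    for (k in seq_len(nrow(st))) {
      if (st$direction[k] == "up") {
        if (is.na(open_frame)) open_frame <- st$frame[k] else multi <- TRUE
      } else if (!is.na(open_frame)) {
        events[[length(events) + 1L]] <-
          list(from = open_frame, to = st$frame[k],
               terminal = if (st$class[k] == "end_of_signal")
                 "separated_or_bleached" else "dissociated",
               multi = multi)
        open_frame <- NA_integer_
        multi <- FALSE
      }
    }
    if (!is.na(open_frame)) {
      events[[length(events) + 1L]] <-
        list(from = open_frame, to = NA_integer_, terminal = "trace_end",
             multi = multi)
    }
    if (!length(events)) return(empty)
    out <- imap(events, function(ev, iev) {
      i0 <- match(ev$from, d$frame)
      i1 <- if (is.na(ev$to)) nrow(d) else {
        cand <- which(d$frame < ev$to)
        if (length(cand)) max(cand) else NA_integer_
      }
      if (is.na(i0) || is.na(i1) || i1 < i0) return(NULL)
      t_end_ev <- if (is.na(ev$to)) d$time_s[i1] + frame_s else
        d$time_s[match(ev$to, d$frame)] %||% (d$time_s[i1] + frame_s)
      if (is.na(t_end_ev)) t_end_ev <- d$time_s[i1] + frame_s
      seg <- seg_event(d$time_s[i0:i1], d$E[i0:i1], frame_s,
                       e_low_max, e_high_min, min_ramp_frames, median_k,
                       t_end_ev, ev$terminal)
      if (nrow(seg) == 0L) return(NULL)
      tibble(event = iev, seg,
             t_bind = d$time_s[i0], t_unbind = t_end_ev,
             terminal_class = ev$terminal, multi_binder = ev$multi)
    })
    out <- list_rbind(out[!vapply(out, is.null, logical(1))])
    if (is.null(out) || nrow(out) == 0L) empty else out
  }

  parts <- fret |>
    group_by(across(all_of(keys))) |>
    group_map(function(d, key) {
      st <- steps
      for (k in names(key)) st <- st[st[[k]] == key[[k]], , drop = FALSE]
      res <- one(d, st)
      if (nrow(res)) bind_cols(key[rep(1L, nrow(res)), , drop = FALSE], res)
      else bind_cols(key[0L, , drop = FALSE],
                     res)
    })
  out <- list_rbind(parts)
  class(out) <- c("substep_annotation", class(out))
  attr(out, "frame_s") <- frame_s
  out
}

#' Count completed unwinding cycles per binding event
#'
#' A cycle is counted whenever unwinding carried the molecule into a stall
#' (one U-S pair), so a final stall cut short by dissociation or trace end
#' still counts the cycle it completed into.
#'
#' @param annotations A [segment_substeps()] result (ground-truth paths from
#'   the simulator work too if relabeled accordingly).
#' @return Tibble `molecule_id` (+`condition`), `event`, `n_cycles`.
#' @export
count_cycles <- function(annotations) {
  keys <- intersect(c("condition", "molecule_id", "event"),
                    names(annotations))
  annotations |>
    summarise(n_cycles = sum(.data$label == "S"), .by = all_of(keys))
}

#' Extract censored dwell times from substep annotations
#'
#' One record per segment plus a `B` (binding wait) record per event: the
#' time from acquisition start -- or from `t0`, the reagent-addition moment
#' in preloading designs -- to the binding up-step. Dwells shorter than half
#' a frame (possible for sub-frame unwinding or stall excursions after
#' quantization) are floored at `frame_s / 2`.
#'
#' @param annotations A [segment_substeps()] result.
#' @param manifest Optional manifest tibble (joined on `condition`).
#' @param t0 Reagent-addition time defining the origin of the B dwell.
#' @param frame_s Frame time; taken from the annotation attribute when
#'   available.
#' @return Tibble: `molecule_id` (+condition columns), `event`, `substep`
#'   (`B`,`A`,`U`,`S`,`R`), `cycle`, `dwell_s`, `censored`.
#' @export
extract_dwells <- function(annotations, manifest = NULL, t0 = 0,
                           frame_s = NULL) {
  if (!is.data.frame(annotations)) {
    abort("`annotations` must be a substep annotation tibble.")
  }
  frame_s <- frame_s %||% attr(annotations, "frame_s") %||% 0.1
  keys <- intersect(c("condition", "molecule_id"), names(annotations))
  if (nrow(annotations) == 0L) {
    return(tibble(molecule_id = integer(0), event = integer(0),
                  substep = character(0), cycle = integer(0),
                  dwell_s = numeric(0), censored = logical(0)))
  }
  bad <- annotations |>
    summarise(overlap = any(diff(.data$t_start) < -1e-9) ||
                any(.data$t_end[-length(.data$t_end)] - 1e-9 >
                      .data$t_start[-1L]),
              .by = all_of(c(keys, "event")))
  if (any(bad$overlap)) {
    abort("Overlapping substep segments; annotation invariant breached.")
  }
  seg_rows <- annotations |>
    mutate(cycle = cumsum(lag(.data$label == "S", default = FALSE)) + 1L,
           .by = all_of(c(keys, "event"))) |>
    transmute(across(all_of(keys)), .data$event, substep = .data$label,
              cycle = as.integer(.data$cycle),
              dwell_s = pmax(.data$t_end - .data$t_start, frame_s / 2),
              censored = .data$censored)
  b_rows <- annotations |>
    distinct(across(all_of(c(keys, "event", "t_bind")))) |>
    transmute(across(all_of(keys)), .data$event, substep = "B",
              cycle = NA_integer_,
              dwell_s = pmax(.data$t_bind - t0, frame_s / 2),
              censored = FALSE)
  out <- bind_rows(b_rows, seg_rows) |>
    arrange(across(all_of(c(keys, "event"))))
  if (!is.null(manifest) && "condition" %in% names(out)) {
    out <- left_join(out, manifest, by = "condition")
  }
  out
}

#' Per-event summaries: total bound time, censoring and cycle count
#'
#' The total bound time (binding up-step to the event's end) underlies the
#' off-rate estimate; it is uncensored only when the event ends in an
#' observed dissociation down-step. Loss of signal (separation or bleach)
#' and trace end censor it.
#'
#' @inheritParams extract_dwells
#' @return Tibble: `molecule_id` (+`condition`), `event`, `t_bind`,
#'   `t_unbind`, `total_bound_s`, `bound_censored`, `n_cycles`,
#'   `terminal_class`, `multi_binder`.
#' @export
event_summary <- function(annotations, manifest = NULL) {
  keys <- intersect(c("condition", "molecule_id"), names(annotations))
  cyc <- count_cycles(annotations)
  out <- annotations |>
    distinct(across(all_of(c(keys, "event", "t_bind", "t_unbind",
                             "terminal_class", "multi_binder")))) |>
    mutate(total_bound_s = .data$t_unbind - .data$t_bind,
           bound_censored = .data$terminal_class != "dissociated") |>
    left_join(cyc, by = c(keys, "event"))
  if (!is.null(manifest) && "condition" %in% names(out)) {
    out <- left_join(out, manifest, by = "condition")
  }
  out
}
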