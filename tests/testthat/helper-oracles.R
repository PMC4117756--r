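# Shared oracles and comparison utilities for the suite.

# Probability that a binding event ends in full strand separation when
# dissociation (hazard k_off) competes with every bound dwell and separation
# ends each completed cycle with probability p_sep (no bleaching, no trace
# truncation): survive A, then a geometric competition over cycles.
sep_fraction_oracle <- function(p, k_u = NULL) {
  k_u <- k_u %||% p$k_unw # saturating ATP unless overridden
  q <- function(k) k / (k + p$k_off)
  qa <- q(p$k_act); qu <- q(k_u); qs <- q(p$k_stall); qr <- q(p$k_react)
  qa * qu * qs * p$p_sep / (1 - (1 - p$p_sep) * qr * qu * qs)
}

# Frame-level comparison of a detected annotation against the simulator's
# ground-truth path for one molecule. Labels must agree on every frame of
# the bound interval except (a) within `tol_frames` of a true segment
# boundary and (b) inside true segments shorter than 3 frames, which fall
# below the sampling resolution. The detected cycle count must lie between
# the number of cycles resolvable at the frame rate (an independent
# sampling oracle: the true FRET trajectory sampled at frame midpoints,
# median-3 filtered, thresholded at the mid band) and the true count.
compare_segmentation <- function(path, segments, frame_s,
                                 tol_frames = 1, e_low = 0.2, e_high = 0.8,
                                 e_mid = 0.5, e_high_min = 0.65) {
  truth <- path[path$label %in% c("A", "U", "S", "R"), , drop = FALSE]
  det <- segments
  if (nrow(truth) == 0L) {
    return(list(ok = nrow(det) == 0L, frac_correct = 1,
                cycles_match = TRUE))
  }
  t0 <- min(truth$t_start); t1 <- max(truth$t_end)
  mids <- seq(floor(t0 / frame_s) * frame_s + frame_s / 2, t1, by = frame_s)
  idx_at <- function(tab, t) {
    i <- findInterval(t, tab$t_start)
    ok <- i >= 1 & t < tab$t_end[pmax(i, 1)] + 1e-9
    i[!ok] <- NA_integer_
    i
  }
  it <- idx_at(truth, mids)
  lt <- ifelse(is.na(it), NA_character_, truth$label[it])
  ld <- ifelse(is.na(idx_at(det, mids)), NA_character_,
               det$label[idx_at(det, mids)])
  bounds <- sort(unique(c(truth$t_start, truth$t_end)))
  near <- vapply(mids, function(t) {
    any(abs(t - bounds) <= tol_frames * frame_s + 1e-9)
  }, logical(1))
  durs <- truth$t_end - truth$t_start
  short <- durs < 3 * frame_s
  # a reactivation dwell following an unresolvable (sub-3-frame) cycle is
  # indistinguishable from continued activation: the positional A/R rule
  # cannot be held to it
  for (i in which(truth$label == "R")) {
    if (i >= 3 && truth$label[i - 1] == "S" && truth$label[i - 2] == "U" &&
        truth$t_end[i - 1] - truth$t_start[i - 2] < 3 * frame_s) {
      short[i] <- TRUE
    }
  }
  bounds2 <- unique(c(truth$t_start[short], truth$t_end[short]))
  if (length(bounds2)) {
    near <- near | vapply(mids, function(t) {
      any(abs(t - bounds2) <= (tol_frames + 1) * frame_s + 1e-9)
    }, logical(1))
  }
  sub_res <- !is.na(it) & short[pmax(it, 1)]
  use <- !near & !sub_res & !is.na(lt)
  agree <- is.na(ld[use]) == FALSE & ld[use] == lt[use]

  # resolvable cycles: true E sampled at midpoints, median-3 filtered
  egen <- rep(e_low, length(mids))
  egen[!is.na(lt) & lt == "S"] <- e_high
  uu <- which(!is.na(lt) & lt == "U")
  if (length(uu)) {
    frac <- (mids[uu] - truth$t_start[it[uu]]) / truth$ramp_T[it[uu]]
    egen[uu] <- e_low + (e_high - e_low) * pmin(1, frac)
  }
  ef <- if (length(egen) >= 3) stats::runmed(egen, 3) else egen
  r <- rle(ef >= e_mid & !is.na(lt))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  vis_runs <- which(r$values)
  n_vis <- 0L
  for (k in vis_runs) {
    idx <- starts[k]:ends[k]
    if (!any(lt[idx] == "S", na.rm = TRUE)) next
    if (k == max(vis_runs) && ends[k] >= length(mids) - 1L) {
      # a terminal stall is distinguishable from a censored ramp only
      # when it lasts a few frames
      s_dur <- sum(lt[idx] == "S", na.rm = TRUE) * frame_s
      if (s_dur < 3 * frame_s) next
    }
    n_vis <- n_vis + 1L
  }
  n_cyc_truth <- sum(truth$label == "S")
  n_cyc_det <- sum(det$label == "S")
  # photobleaching mid-ramp is observationally identical to separation
  # right after stall entry, so one extra apparent cycle is tolerated on
  # bleach-terminated paths
  bleach_slop <- as.integer(identical(attr(path, "terminal"), "bleached"))
  cycles_match <- n_cyc_det >= n_vis &&
    n_cyc_det <= n_cyc_truth + bleach_slop
  list(ok = all(agree) && cycles_match,
       frac_correct = if (any(use)) mean(agree) else 1,
       cycles_match = cycles_match,
       n_compared = sum(use))
}

# TRUE when the molecule shows an unbound baseline of at least `n` frames
# before binding; a trace that starts already bound has no intensity step
# to find.
has_baseline <- function(path, frame_s, n = 3) {
  ub <- path[path$label == "unbound", , drop = FALSE]
  nrow(ub) > 0 && (ub$t_end[1] - ub$t_start[1]) >= n * frame_s
}

# Simulate a dataset and run the analysis chain with default thresholds.
sim_and_analyze <- function(params, conds, n, duration_s, seed, ...) {
  ds <- simulate_dataset(params, conds, n_molecules = n,
                         duration_s = duration_s, seed = seed)
  list(ds = ds, an = analyze_traces(ds$traces, ...))
}
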