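trace_cols <- c("molecule_id", "frame", "time_s", "I_D", "I_A")

validate_traces <- function(traces, arg = "traces") {
  if (!is.data.frame(traces) || nrow(traces) == 0L) {
    abort(paste0("`", arg, "` must be a non-empty data frame of per-frame ",
                 "intensities."))
  }
  missing <- setdiff(trace_cols, names(traces))
  if (length(missing)) {
    abort(paste0("`", arg, "` is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- traces$molecule_id[!is.finite(traces$I_D) | !is.finite(traces$I_A)]
  if (length(bad)) {
    abort(paste0("Non-finite intensities for molecule(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  mono <- traces |>
    summarise(ok = all(diff(.data$frame) > 0),
              .by = any_of(c("condition", "molecule_id")))
  if (!all(mono$ok)) {
    abort(paste0("Frame indices not strictly increasing for molecule(s): ",
                 paste(unique(mono$molecule_id[!mono$ok]), collapse = ", ")))
  }
  invisible(traces)
}

# Monotone validity mask: frames become (and stay) invalid from the first
# sustained run of at-floor totals, so isolated noise dips do not truncate a
# live trace while a dark (bleached / strand-lost) tail is excluded.
mask_live <- function(total, floor, run = 3L) {
  below <- total <= floor
  if (!any(below)) return(rep(TRUE, length(total)))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run)
  if (!length(hit)) return(rep(TRUE, length(total)))
  dark_from <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  seq_along(total) < dark_from
}

# Robust per-channel-sum noise SD from first differences (steps are sparse).
total_noise_sd <- function(total) {
  if (length(total) < 3L) return(0)
  stats::mad(diff(total)) / sqrt(2)
}

#' Compute FRET efficiency and total intensity per frame
#'
#' FRET is `I_A / (I_D + I_A)` and total intensity `I_D + I_A`. Frames are
#' masked invalid from the first frame whose total falls to the floor
#' (photobleaching / strand loss); the mask is monotone, so once a molecule
#' goes dark it stays excluded. Raw FRET (which noise can push outside
#' \[0, 1\]) is kept alongside a clamped copy used for histogramming.
#'
#' @param traces Per-frame intensity tibble with columns `molecule_id`,
#'   `frame`, `time_s`, `I_D`, `I_A` (a `condition` column, if present, is
#'   carried through). Accepts the `$traces` element of a
#'   [simulate_dataset()] result or a [simulate_trace()] `$trace`.
#' @param total_floor Validity floor on total intensity. `NULL` (default)
#'   estimates it per molecule as five noise SDs above zero background, which
#'   reduces to "total > 0" for noiseless traces.
#' @param clamp Ignored frames aside, should `E_clamp` be clamped to \[0, 1\]?
#' @return Tibble of class `fret_trace`: `molecule_id`, (`condition`,)
#'   `frame`, `time_s`, `E`, `E_clamp`, `total`, `valid`.
#' @examples
#' tr <- tibble::tibble(molecule_id = 0L, frame = 0:1, time_s = c(0, 0.1),
#'                      I_D = c(100, 60), I_A = c(100, 140))
#' compute_fret(tr)
#' @export
compute_fret <- function(traces, total_floor = NULL, clamp = TRUE) {
  if (is.list(traces) && !is.data.frame(traces) && !is.null(traces$trace)) {
    traces <- traces$trace
  }
  validate_traces(traces)
  keys <- intersect(c("condition", "molecule_id"), names(traces))
  out <- traces |>
    mutate(
      total = .data$I_D + .data$I_A,
      E = ifelse(.data$total != 0, .data$I_A / .data$total, NA_real_),
      .by = all_of(keys)
    ) |>
    mutate(
      valid = mask_live(.data$total,
                        total_floor %||% (5 * total_noise_sd(.data$total))),
      .by = all_of(keys)
    ) |>
    mutate(E_clamp = if (clamp) pmin(pmax(.data$E, 0), 1) else .data$E) |>
    select(all_of(keys), "frame", "time_s", "E", "E_clamp", "total", "valid")
  class(out) <- c("fret_trace", class(out))
  out
}

#' Detect photobleaching from the total-intensity channel
#'
#' Finds, per molecule, the first frame from which the total intensity stays
#' within noise of the background for at least `min_run` frames. Strand
#' separation produces the same signature (both dyes leave with the unwound
#' strand); downstream analysis treats either as the end of the usable trace.
#'
#' @param fret A [compute_fret()] result.
#' @param background Background total-intensity level (same units as the
#'   trace; default 0).
#' @param min_run Minimum run length of background-level frames (>= 1).
#' @param tol Half-width of the noise band around background. `NULL`
#'   estimates 3 noise SDs per molecule.
#' @return Tibble `molecule_id` (+`condition`), `bleach_frame` (0-based, `NA`
#'   if the signal persists to the end).
#' @export
detect_bleach <- function(fret, background = 0, min_run = 5L, tol = NULL) {
  if (min_run < 1) abort("`min_run` must be >= 1.")
  keys <- intersect(c("condition", "molecule_id"), names(fret))
  fret |>
    summarise(
      bleach_frame = {
        lim <- background + (tol %||% (3 * total_noise_sd(.data$total)))
        below <- .data$total <= lim
        r <- rle(below)
        ends <- cumsum(r$lengths)
        hit <- which(r$values & r$lengths >= min_run)
        if (length(hit)) {
          .data$frame[ends[hit[1]] - r$lengths[hit[1]] + 1L]
        } else NA_integer_
      },
      .by = all_of(keys)
    )
}

# Offline change-point detection on a single numeric series by binary
# segmentation with the standardized CUSUM statistic. The noise scale is
# estimated robustly from first differences (steps are sparse), the split
# position is the exact two-mean least-squares argmax, and splits recurse
# until no candidate exceeds the Bonferroni-style threshold. Returns the
# 1-based indices of the first sample of each new level.
step_scan_multi <- function(x, w, alpha) {
  n <- length(x)
  if (n < 2 * w) {
    abort("Trace shorter than 2 * window frames; cannot scan for steps.")
  }
  sigma <- stats::mad(diff(x)) / sqrt(2)
  thresh <- stats::qnorm(1 - alpha / (2 * n))
  min_seg <- 3L
  bp <- integer(0)
  split_seg <- function(l, r) {
    m <- r - l + 1L
    if (m < 2L * min_seg) return(invisible(NULL))
    seg <- x[l:r]
    cs <- cumsum(seg)
    k <- min_seg:(m - min_seg) # split after the k-th sample of the segment
    mL <- cs[k] / k
    mR <- (cs[m] - cs[k]) / (m - k)
    scale <- sqrt(k * (m - k) / m)
    d <- abs(mR - mL) * scale
    j <- which.max(d) # exact two-mean least-squares split
    th <- if (sigma > 0) thresh * sigma else
      1e-8 * (max(abs(seg)) + 1) # noiseless: any real level shift
    if (d[j] < th) return(invisible(NULL))
    cut <- l + k[j] # first sample of the new level (global index)
    bp <<- c(bp, cut)
    split_seg(l, cut - 1L)
    split_seg(cut, r)
    invisible(NULL)
  }
  split_seg(1L, n)
  sort(bp)
}

#' Detect protein binding/dissociation steps in total intensity
#'
#' Protein binding near the dye enhances total fluorescence (PIFE), so the
#' total-intensity channel carries abrupt up-steps at binding and down-steps
#' at dissociation or loss of signal. A sliding Welch-style two-sample scan
#' with a Bonferroni-adjusted threshold flags change points; boundaries are
#' refined by an exact local two-mean fit and levels reported as segment
#' means. Down-steps that land at background are classified `end_of_signal`
#' (bleach or full strand separation), other down-steps `dissociation`.
#'
#' @param fret A [compute_fret()] result.
#' @param window Frames per side of the sliding comparison (>= 2).
#' @param alpha Per-trace family-wise false-positive level.
#' @param background Background total-intensity level.
#' @return Tibble of class `step_events`: `molecule_id` (+`condition`),
#'   `frame` (0-based first frame of the new level), `time_s`, `direction`
#'   (`"up"`/`"down"`), `pre_level`, `post_level`, `class` (`binding`,
#'   `dissociation`, `end_of_signal`). Zero rows if no step is found.
#' @export
detect_intensity_steps <- function(fret, window = 10L, alpha = 0.01,
                                   background = 0) {
  if (window < 2) abort("`window` must be >= 2 frames.")
  keys <- intersect(c("condition", "molecule_id"), names(fret))
  frame_s <- infer_frame_s(fret)
  one <- function(d) {
    x <- d$total
    bp <- step_scan_multi(x, as.integer(window), alpha)
    if (!length(bp)) {
      return(tibble(frame = integer(0), time_s = numeric(0),
                    direction = character(0), pre_level = numeric(0),
                    post_level = numeric(0), class = character(0)))
    }
    bounds <- c(1L, bp, length(x) + 1L)
    levels <- vapply(seq_len(length(bounds) - 1L), function(k) {
      mean(x[bounds[k]:(bounds[k + 1L] - 1L)])
    }, numeric(1))
    top <- max(levels)
    tibble(
      frame = d$frame[bp],
      time_s = d$time_s[bp],
      direction = ifelse(diff(levels) > 0, "up", "down"),
      pre_level = levels[-length(levels)],
      post_level = levels[-1L],
    ) |>
      mutate(class = case_when(
        .data$direction == "up" ~ "binding",
        .data$post_level <= background + 0.25 * (top - background) ~
          "end_of_signal",
        TRUE ~ "dissociation"
      ))
  }
  out <- fret |>
    reframe(one(pick(everything())), .by = all_of(keys))
  class(out) <- c("step_events", class(out))
  attr(out, "frame_s") <- frame_s
  out
}

infer_frame_s <- function(fret) {
  d <- diff(fret$time_s)
  d <- d[d > 0]
  if (!length(d)) return(NA_real_)
  stats::median(d)
}

#' Population FRET histogram from the initial frames of each trace
#'
#' Pools the first `n_frames` valid frames of every molecule (the standard
#' snapshot histogram built from the initial 10 frames of each trace) and
#' returns a normalized histogram of clamped FRET on \[0, 1\].
#'
#' @param fret A [compute_fret()] result (any number of molecules).
#' @param n_frames Initial valid frames used per molecule.
#' @param bins Number of equal-width bins on \[0, 1\].
#' @return Tibble of class `fret_histogram` with `bin_left`, `bin_right`,
#'   `prob` (summing to 1); attributes `n_molecules`, `n_frames`, `n_obs`.
#' @export
build_fret_histogram <- function(fret, n_frames = 10L, bins = 50L) {
  dat <- fret |>
    filter(.data$valid, is.finite(.data$E_clamp)) |>
    slice_head(n = as.integer(n_frames),
               by = any_of(c("condition", "molecule_id")))
  if (nrow(dat) == 0L) {
    abort("No valid frames in any trace; cannot build a FRET histogram.")
  }
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(dat$E_clamp, edges, rightmost.closed = TRUE),
                   1L), bins)
  counts <- tabulate(idx, nbins = bins)
  out <- tibble(bin_left = edges[-length(edges)], bin_right = edges[-1L],
                prob = counts / sum(counts))
  mol_key <- if ("condition" %in% names(dat)) {
    paste(dat$condition, dat$molecule_id)
  } else dat$molecule_id
  attr(out, "n_molecules") <- n_distinct(mol_key)
  attr(out, "n_frames") <- as.integer(n_frames)
  attr(out, "n_obs") <- nrow(dat)
  class(out) <- c("fret_histogram", class(out))
  out
}
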