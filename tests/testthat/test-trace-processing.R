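make_trace <- function(I_D, I_A, frame_s = 0.1, id = 0L) {
  n <- length(I_D)
  tibble::tibble(molecule_id = id, frame = seq_len(n) - 1L,
                 time_s = (seq_len(n) - 1L) * frame_s, I_D = I_D, I_A = I_A)
}

test_that("FRET and total intensity follow their definitions", {
  tr <- make_trace(c(100, 300, 60), c(100, 0, 140))
  f <- compute_fret(tr)
  expect_equal(f$E, c(0.5, 0.0, 0.7))
  expect_equal(f$total, c(200, 300, 200))
  # round trip: (E*T, (1-E)*T) reconstructs the channels
  expect_equal(f$E * f$total, tr$I_A, tolerance = 1e-9)
  expect_equal((1 - f$E) * f$total, tr$I_D, tolerance = 1e-9)
  expect_error(compute_fret(tr[0, ]), "non-empty")
  expect_error(compute_fret(make_trace(c(1, NaN), c(1, 1))), "Non-finite")
  bad <- make_trace(c(1, 2), c(1, 2)); bad$frame <- c(1L, 1L)
  expect_error(compute_fret(bad), "increasing")
  expect_error(compute_fret(dplyr::select(tr, -I_A)), "I_A")
})

test_that("the validity mask is monotone and floors dark frames", {
  tr <- make_trace(c(rep(100, 10), rep(0, 5), rep(100, 3)),
                   c(rep(100, 10), rep(0, 5), rep(100, 3)))
  f <- compute_fret(tr)
  expect_true(all(f$valid[1:10]))
  expect_false(any(f$valid[11:18])) # once dark, stays invalid
  expect_true(all(is.na(f$E[11:15])))
})

test_that("bleach detection finds the dark transition", {
  T_half <- c(rep(200, 80), rep(0, 40))
  tr <- make_trace(T_half / 2, T_half / 2)
  f <- compute_fret(tr, total_floor = 0)
  expect_equal(detect_bleach(f, min_run = 5)$bleach_frame, 80L)
  live <- make_trace(rep(100, 60), rep(100, 60))
  expect_true(is.na(detect_bleach(compute_fret(live))$bleach_frame))
  expect_error(detect_bleach(f, min_run = 0), ">= 1")
})

test_that("bleach localization is frame-accurate under noise", {
  set.seed(42)
  hits <- vapply(1:500, function(i) {
    bf <- sample(40:160, 1)
    total <- c(rep(300, bf), rep(0, 200 - bf)) + rnorm(200, 0, 30)
    tr <- make_trace(total / 2 + rnorm(200, 0, 10),
                     total / 2 + rnorm(200, 0, 10))
    f <- compute_fret(tr, total_floor = -Inf)
    abs((detect_bleach(f, tol = 90, min_run = 5)$bleach_frame %||% 1e6) -
          bf) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("noiseless intensity steps are localized exactly", {
  total <- c(rep(200, 50), rep(300, 70))
  tr <- make_trace(total * 0.8, total * 0.2)
  st <- detect_intensity_steps(compute_fret(tr), window = 10)
  expect_equal(nrow(st), 1L)
  expect_equal(st$frame, 50L)
  expect_equal(st$direction, "up")
  expect_equal(st$class, "binding")
  expect_equal(st$pre_level, 200)
  expect_equal(st$post_level, 300)

  flat <- make_trace(rep(160, 100), rep(40, 100))
  expect_equal(nrow(detect_intensity_steps(compute_fret(flat))), 0L)
  expect_error(detect_intensity_steps(compute_fret(flat), window = 1),
               ">= 2")
  short <- make_trace(rep(1, 10), rep(1, 10))
  expect_error(detect_intensity_steps(compute_fret(short), window = 10),
               "shorter")
})

test_that("binding steps are recovered within 2 frames at 10% noise", {
  # PIFE step 200 -> 300 with per-channel sigma = 10% of I_total
  set.seed(7)
  hits <- vapply(1:500, function(i) {
    bf <- sample(60:140, 1)
    total <- c(rep(200, bf), rep(300, 200 - bf))
    tr <- make_trace(total * 0.8 + rnorm(200, 0, 20),
                     total * 0.2 + rnorm(200, 0, 20))
    st <- detect_intensity_steps(compute_fret(tr, total_floor = -Inf),
                                 window = 10)
    up <- st$frame[st$direction == "up"]
    length(up) >= 1 && any(abs(up - bf) <= 2)
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("false-positive step rate on flat noisy traces is controlled", {
  set.seed(13)
  fp <- vapply(1:500, function(i) {
    total <- rep(200, 600)
    tr <- make_trace(total * 0.8 + rnorm(600, 0, 20),
                     total * 0.2 + rnorm(600, 0, 20))
    nrow(detect_intensity_steps(compute_fret(tr, total_floor = -Inf),
                                window = 10, alpha = 0.01)) > 0
  }, logical(1))
  expect_lte(mean(fp), 0.05)
})

test_that("histograms are built from initial valid frames and normalize", {
  tr1 <- make_trace(rep(160, 30), rep(40, 30), id = 0L)  # E = 0.2
  f <- compute_fret(tr1)
  for (b in c(20, 50, 97)) {
    h <- build_fret_histogram(f, bins = b)
    expect_equal(sum(h$prob), 1, tolerance = 1e-9)
    expect_equal(sum(h$prob[h$bin_left <= 0.2 & h$bin_right >= 0.2]), 1,
                 tolerance = 1e-9)
  }
  # frames 10+ at high FRET must not contaminate the 10-frame histogram
  tr2 <- make_trace(c(rep(160, 10), rep(40, 40)),
                    c(rep(40, 10), rep(160, 40)), id = 1L)
  h2 <- build_fret_histogram(compute_fret(tr2), n_frames = 10)
  expect_equal(sum(h2$prob[h2$bin_right <= 0.5]), 1, tolerance = 1e-9)
  dark <- compute_fret(make_trace(rep(0, 5), rep(0, 5)), total_floor = 0)
  expect_error(build_fret_histogram(dark), "valid")
})

test_that("ATP-driven unwinding adds a high-FRET population", {
  p <- sim_params()
  conds <- list(atp = condition(atp_uM = 1000), no_atp = condition(atp_uM = 0))
  pools <- lapply(seq_along(conds), function(i) {
    ds <- simulate_dataset(p, conds[[i]], n_molecules = 600,
                           duration_s = 1, seed = 40 + i, obs_start_s = 60)
    f <- compute_fret(ds$traces)
    dplyr::slice_head(dplyr::filter(f, .data$valid), n = 10,
                      by = "molecule_id")$E_clamp
  })
  expect_gt(mean(pools[[1]] > 0.6), mean(pools[[2]] > 0.6) + 0.05)
  ks <- suppressWarnings(stats::ks.test(pools[[1]], pools[[2]]))
  expect_lt(ks$p.value, 0.01)
})
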