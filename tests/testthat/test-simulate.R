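test_that("an absorbing bound state pins the observation model", {
  # all rates zero except binding: once bound the molecule sits in the
  # activation state forever at E_low with the PIFE-enhanced total
  p <- sim_params(k_act = 0, k_unw = 0, k_stall = 0, k_react = 0,
                  k_off = 0, k_bleach = 0, sigma_noise = 0,
                  pife_gamma = 1.5, I_total = 200)
  tr <- simulate_trace(p, condition(rha_nM = 400), duration_s = 60,
                       seed = 11)
  f <- compute_fret(tr$trace)
  bind_t <- tr$path$t_start[tr$path$label == "A"]
  bound <- f$time_s >= bind_t
  expect_true(any(bound))
  expect_true(all(abs(f$total[bound] - 300) < 1e-9))
  expect_true(all(abs(f$E[bound] - p$E_low) < 1e-12))
  expect_true(all(abs(f$total[!bound] - 200) < 1e-9))
})

test_that("same seed gives identical traces, different seeds differ", {
  p <- sim_params()
  a <- simulate_trace(p, condition(), 30, seed = 5)
  b <- simulate_trace(p, condition(), 30, seed = 5)
  c <- simulate_trace(p, condition(), 30, seed = 6)
  expect_identical(a$trace, b$trace)
  expect_identical(a$path, b$path)
  expect_false(identical(a$trace, c$trace))
})

test_that("state paths satisfy the cycle grammar and partition time", {
  p <- sim_params()
  for (seed in 1:40) {
    pa <- simulate_trace(p, condition(), 120, seed = seed)$path
    expect_true(all(diff(pa$t_start) >= 0))
    expect_equal(pa$t_start[-1], pa$t_end[-nrow(pa)], tolerance = 1e-12)
    expect_equal(pa$t_start[1], 0)
    term <- pa$label %in% c("separated", "dissociated", "bleached")
    expect_lte(sum(term), 1L)
    if (any(term)) expect_equal(which(term), nrow(pa))
    lab <- pa$label[pa$label %in% c("A", "U", "S", "R")]
    if (length(lab)) {
      # uncensored bound sequences follow A (U S R)* (U S)?
      body <- paste(lab, collapse = "")
      expect_match(body, "^A(USR)*(US?)?$")
    }
  }
})

test_that("noiseless frames reproduce the generating FRET exactly", {
  p <- sim_params(sigma_noise = 0)
  tr <- simulate_trace(p, condition(), 100, seed = 21)
  f <- compute_fret(tr$trace)
  pa <- tr$path
  live <- f$valid
  # reconstruct the generating E at each frame midpoint from the path
  mid <- f$time_s + p$frame_s / 2
  idx <- findInterval(mid, pa$t_start)
  lab <- pa$label[idx]
  egen <- rep(p$E_low, length(mid))
  egen[lab == "S"] <- p$E_high
  u <- which(lab == "U")
  egen[u] <- p$E_low + (p$E_high - p$E_low) *
    pmin(1, (mid[u] - pa$t_start[idx[u]]) / pa$ramp_T[idx[u]])
  keep <- live & !lab %in% c("bleached", "separated")
  expect_true(all(abs(f$E[keep] - egen[keep]) < 1e-12))
})

test_that("substep dwells match their generating exponentials", {
  # competing hazards off so every dwell is a pure Exp(k) draw
  p <- sim_params(k_off = 0, k_bleach = 0, p_sep = 0.15)
  dw <- list(A = c(), U = c(), S = c(), R = c())
  for (seed in 1:2100) {
    pa <- simulate_trace(p, condition(), 300, seed = seed)$path
    keep <- pa$label %in% names(dw) & !pa$censored
    for (l in unique(pa$label[keep])) {
      d <- pa[keep & pa$label == l, ]
      dw[[l]] <- c(dw[[l]], d$t_end - d$t_start)
    }
  }
  gen <- c(A = p$k_act, U = p$k_unw * (1e-3 / (p$Km_atp + 1e-3)),
           S = p$k_stall, R = p$k_react)
  for (l in names(dw)) {
    x <- dw[[l]]
    expect_gt(length(x), 2000)
    se <- mean(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - 1 / gen[[l]]), 3 * se)
  }
})

test_that("strand-separation frequency matches the competition closed form", {
  p <- sim_params(k_bleach = 0, sigma_noise = 0)
  k_u <- p$k_unw * (1e-3 / (p$Km_atp + 1e-3))
  expected <- sep_fraction_oracle(p, k_u)
  n <- 1500
  outcomes <- vapply(seq_len(n), function(seed) {
    pa <- simulate_trace(p, condition(), 2000, seed = seed + 10000)$path
    attr(pa, "terminal")
  }, character(1))
  bound <- outcomes %in% c("separated", "dissociated")
  expect_gt(mean(bound), 0.95) # long traces: events nearly always resolve
  phat <- mean(outcomes[bound] == "separated")
  se <- sqrt(expected * (1 - expected) / sum(bound))
  expect_lt(abs(phat - expected), 3 * se)
})

test_that("wild-type events cycle a median of 2-10 times", {
  p <- sim_params()
  cyc <- vapply(1:400, function(seed) {
    pa <- simulate_trace(p, condition(), 500, seed = seed + 500)$path
    attr(pa, "n_cycles")
  }, integer(1))
  med <- median(as.numeric(cyc))
  expect_gte(med, 2)
  expect_lte(med, 10)
})

test_that("datasets are reproducible and carry the condition grid", {
  p <- sim_params()
  ds <- simulate_dataset(p, condition(), n_molecules = 3, duration_s = 10,
                         seed = 7)
  expect_setequal(unique(ds$traces$molecule_id), 0:2)
  ds2 <- simulate_dataset(p, condition(), n_molecules = 3, duration_s = 10,
                          seed = 7)
  expect_identical(ds$traces, ds2$traces)
  expect_identical(ds$paths, ds2$paths)

  grid <- condition(atp_uM = c(10, 25, 50, 100, 250, 500, 1000))
  dg <- simulate_dataset(p, grid, n_molecules = 1, duration_s = 5, seed = 1)
  expect_equal(sort(unique(dg$manifest$atp_conc)),
               sort(grid$atp_conc))
  expect_equal(nrow(dg$manifest), 7L)
  expect_error(simulate_dataset(p, condition()[0, ], 3, 10, seed = 1),
               "at least one row")
  expect_error(simulate_dataset(p, condition(), 0, 10, seed = 1), ">= 1")
  expect_error(simulate_trace(p, condition(), -2, seed = 1), "positive")
  expect_error(simulate_trace(sim_params(k_act = Inf), condition(), 5,
                              seed = 1), "finite")
})

test_that("annealing fields follow the exponential law by condition", {
  p <- sim_params()
  no_prot <- simulate_annealing_field(p, condition(rha_nM = 0), 400,
                                      c(0, 100, 300, 600), TRUE, seed = 2)
  expect_true(all(no_prot$annealed == 0))

  fast <- sim_params(k_anneal_unwind = 1e6)
  inst <- simulate_annealing_field(fast, condition(), 200, c(1, 10), TRUE,
                                   seed = 3)
  expect_equal(inst$annealed[1], 200L)

  # empirical annealed-fraction curve vs the analytic CDF 1 - exp(-kt)
  tc <- simulate_annealing_field(p, condition(), 2000,
                                 snapshot_times = seq(30, 600, by = 30),
                                 include_atp = TRUE, seed = 4)
  k <- attr(tc, "k_true")
  times <- attr(tc, "anneal_times")
  ks <- suppressWarnings(stats::ks.test(times, "pexp", k))
  expect_gt(ks$p.value, 0.01)
  frac <- tc$annealed / tc$total
  expect_true(all(abs(frac - (1 - exp(-k * tc$time_s))) <
                    4 * sqrt(0.25 / tc$total)))
  expect_error(simulate_annealing_field(p, condition(), 0, c(0, 1), TRUE),
               ">= 1")
  expect_error(simulate_annealing_field(p, condition(), 10, c(5), TRUE),
               "increasing")
})
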