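test_that("the exponential rate estimator is 1/mean with delta-method SEM", {
  est <- estimate_rate(c(2, 2, 2))
  expect_equal(est$rate, 0.5)
  expect_equal(est$sem, 0.5 / sqrt(3))
  expect_equal(est$n, 3L)
  expect_error(estimate_rate(numeric(0)), "non-empty")
  all_cens <- tibble::tibble(substep = "A", dwell_s = c(1, 2),
                             censored = TRUE)
  expect_error(estimate_rate(all_cens), "A")
  # censored dwells are excluded and counted
  mix <- tibble::tibble(dwell_s = c(2, 2, 2, 50), censored = c(rep(FALSE, 3), TRUE))
  est2 <- estimate_rate(mix)
  expect_equal(est2$rate, 0.5)
  expect_equal(est2$n_censored, 1L)
})

test_that("rate estimation is consistent and nearly unbiased", {
  set.seed(1)
  x <- rexp(1000, 0.1)
  est <- estimate_rate(x)
  expect_lt(abs(est$rate - 0.1), 3 * est$sem)
  # bias at n = 1000 below 1%
  set.seed(2)
  ests <- vapply(1:400, function(i) 1 / mean(rexp(1000, 0.1)), numeric(1))
  expect_lt(abs(mean(ests) - 0.1) / 0.1, 0.01)
  # bootstrap SEM agrees with the delta method at large n
  bs <- estimate_rate(tibble::tibble(dwell_s = x), sem_method = "bootstrap")
  expect_lt(abs(bs$sem - est$sem) / est$sem, 0.3)
})

test_that("off rates come from total bound times", {
  expect_equal(estimate_off_rate(c(10, 10))$rate, 0.1)
  ev <- tibble::tibble(total_bound_s = c(5, 10, 200),
                       bound_censored = c(FALSE, FALSE, TRUE))
  est <- estimate_off_rate(ev)
  expect_equal(est$rate, 1 / 7.5)
  expect_equal(est$n_censored, 1L)
})

test_that("the mutant dissociates faster and wild-type off rate is [RHA]-flat", {
  wt <- preset_params("wild_type", sigma_noise = 0)
  mut <- preset_params("delta_dsRBD", sigma_noise = 0)
  off_of <- function(p, rha, seeds, duration) {
    bt <- c()
    for (s in seeds) {
      pa <- simulate_trace(p, condition(rha_nM = rha), duration,
                           seed = s)$path
      if (attr(pa, "terminal") == "dissociated") {
        bound <- pa[pa$label %in% c("A", "U", "S", "R"), ]
        bt <- c(bt, max(bound$t_end) - min(bound$t_start))
      }
    }
    estimate_off_rate(bt)
  }
  o_mut <- off_of(mut, 320, 1:150, 300)
  o_wt <- off_of(wt, 40, 1:150, 300)
  expect_gt(o_mut$rate - o_wt$rate, 2 * sqrt(o_mut$sem^2 + o_wt$sem^2))
  # flatness across 10-80 nM: slope CI contains 0
  offs <- purrr::map_dfr(c(10, 20, 40, 80), function(rha) {
    est <- off_of(wt, rha, 1:120 + rha * 1000, 400)
    tibble::tibble(rha_conc = rha * 1e-9, rate = est$rate, sem = est$sem)
  })
  fit <- lm(rate ~ rha_conc, data = offs, weights = 1 / sem^2)
  ci <- confint(fit)["rha_conc", ]
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("association-constant fits recover the slope", {
  conc <- c(10, 20, 40, 80) * 1e-9
  exact <- tibble::tibble(conc = conc, rate = 2.61e6 * conc)
  fit <- suppressWarnings( # lm warns on an exactly collinear fit
    fit_association_constant(exact, conc_col = "conc"))
  expect_equal(fit$slope, 2.61e6, tolerance = 1e-9)
  expect_equal(fit$intercept, 0)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-9)

  zero <- tibble::tibble(conc = conc, rate = rep(0, 4))
  expect_equal(fit_association_constant(zero, conc_col = "conc")$slope, 0)
  expect_error(fit_association_constant(exact[1, ], conc_col = "conc"),
               "two distinct")

  # end-to-end: binding dwells simulated per concentration
  set.seed(11)
  rates <- purrr::map_dfr(conc, function(cc) {
    estimate_rate(rexp(200, 2.61e6 * cc)) |>
      dplyr::mutate(conc = cc)
  })
  fit2 <- fit_association_constant(rates, conc_col = "conc",
                                   sem_col = "sem")
  expect_lt(abs(fit2$slope - 2.61e6), 3 * fit2$slope_se)
  td <- tidy(fit2)
  expect_equal(td$term, "slope")
})

test_that("Michaelis-Menten fits recover Vmax and Km", {
  x <- c(10, 25, 50, 100, 250, 500, 1000) * 1e-6
  exact <- tibble::tibble(atp = x, rate = 1 * x / (26e-6 + x))
  fit <- fit_michaelis_menten(exact, conc_col = "atp")
  expect_true(fit$converged)
  expect_equal(fit$vmax, 1, tolerance = 1e-6)
  expect_equal(fit$km, 26e-6, tolerance = 1e-6)

  # saturating-only data leave Km unconstrained
  sat <- tibble::tibble(atp = c(5e-3, 1e-2, 5e-2),
                        rate = c(0.999, 1.0005, 1.0003))
  fs <- fit_michaelis_menten(sat, conc_col = "atp")
  expect_true(!fs$converged || !is.finite(fs$km_se) ||
                fs$km_se / fs$km > 0.5)
  expect_error(fit_michaelis_menten(exact[1:2, ], conc_col = "atp"),
               "three distinct")

  # end-to-end recovery from simulated unwinding dwells
  set.seed(21)
  rates <- purrr::map_dfr(x, function(cc) {
    estimate_rate(rexp(200, 1 * cc / (26e-6 + cc))) |>
      dplyr::mutate(atp = cc)
  })
  fit2 <- fit_michaelis_menten(rates, conc_col = "atp", sem_col = "sem")
  expect_true(fit2$converged)
  expect_lt(abs(fit2$km - 26e-6), 3 * fit2$km_se)
  expect_equal(nrow(tidy(fit2)), 2L)
})

test_that("fold changes propagate errors and recover the 37C scaling", {
  r1 <- tibble::tibble(substep = c("A", "U"), rate = c(0.1, 0.5),
                       sem = c(0.01, 0.05))
  expect_equal(fold_change(r1, r1)$ratio, c(1, 1))
  r2 <- r1; r2$substep <- c("A", "S")
  expect_error(fold_change(r1, r2), "labels")

  p <- sim_params(sigma_noise = 0)
  rates_at <- function(temp, seeds) {
    dw <- purrr::map_dfr(seeds, function(s) {
      pa <- simulate_trace(p, condition(temperature = temp), 200,
                           seed = s)$path
      pa |>
        dplyr::filter(.data$label %in% c("A", "U", "S", "R"),
                      !.data$censored) |>
        dplyr::transmute(substep = .data$label,
                         dwell_s = .data$t_end - .data$t_start,
                         censored = FALSE)
    })
    estimate_rate(dw)
  }
  fc <- fold_change(rates_at("RT", 1:250), rates_at("37C", 251:500))
  expect_setequal(fc$substep, c("A", "U", "S", "R"))
  # every substep accelerated by the generating factor 3, inside the
  # 2-5x band
  expect_true(all(fc$conf_low <= 3 & 3 <= fc$conf_high))
  expect_true(all(fc$ratio >= 2 & fc$ratio <= 5))
})

test_that("binding isotherms recover Kd and flag flat titrations", {
  conc <- c(0, 5, 10, 25, 50, 100, 250, 500) * 1e-9
  pol <- 50 + (200 - 50) * conc / (50e-9 + conc)
  fit <- fit_binding_isotherm(tibble::tibble(conc = conc, pol = pol))
  expect_true(fit$converged)
  expect_equal(fit$kd, 50e-9, tolerance = 1e-6)
  expect_true(fit$identifiable)

  flat <- fit_binding_isotherm(tibble::tibble(conc = conc,
                                              pol = rep(100, 8)))
  expect_false(isTRUE(flat$identifiable))
  expect_error(fit_binding_isotherm(tibble::tibble(conc = conc[1:3],
                                                   pol = pol[1:3])),
               "four")

  # noisy recovery study: median Kd within 10% of truth
  set.seed(31)
  kds <- vapply(1:300, function(i) {
    noisy <- pol * (1 + rnorm(length(pol), 0, 0.05))
    fit_binding_isotherm(tibble::tibble(conc = conc, pol = noisy))$kd
  }, numeric(1))
  expect_lt(abs(median(kds, na.rm = TRUE) - 50e-9) / 50e-9, 0.1)
})

test_that("full substep-rate recovery from a simulated experiment", {
  p <- sim_params() # default noise, 40 nM RHA, 1 mM ATP
  res <- sim_and_analyze(p, condition(), n = 170, duration_s = 150,
                         seed = 101)
  rates <- res$an$rates
  gen <- c(B = p$k_on * 40e-9, A = p$k_act,
           U = p$k_unw * 1e-3 / (p$Km_atp + 1e-3),
           S = p$k_stall, R = p$k_react)
  for (s in names(gen)) {
    row <- rates[rates$substep == s, ]
    expect_gt(row$n, 100)
    expect_lt(abs(row$rate - gen[[s]]), 3 * row$sem)
  }
  # activation is the slowest substep under the defaults
  expect_equal(rates$substep[which.min(rates$rate)], "A")
})
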