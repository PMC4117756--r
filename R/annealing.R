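#' Annealed fraction versus time with Wilson confidence intervals
#'
#' Converts annealed-molecule counts into fractions per snapshot and attaches
#' Wilson score intervals for the binomial proportion.
#'
#' @param timecourse Tibble with columns `time_s`, `annealed`, `total`
#'   (e.g. from [simulate_annealing_field()]).
#' @param conf_level Confidence level for the Wilson interval.
#' @return Tibble of class `annealing_curve`: `time_s`, `annealed`, `total`,
#'   `fraction`, `conf_low`, `conf_high`.
#' @examples
#' tc <- tibble::tibble(time_s = c(0, 60, 120), annealed = c(0, 30, 50),
#'                      total = 100)
#' annealing_fraction_curve(tc)
#' @export
annealing_fraction_curve <- function(timecourse, conf_level = 0.95) {
  need <- c("time_s", "annealed", "total")
  if (!all(need %in% names(timecourse))) {
    abort("`timecourse` needs columns time_s, annealed, total.")
  }
  if (any(timecourse$total <= 0)) abort("Totals must be > 0.")
  if (any(timecourse$annealed > timecourse$total)) {
    abort("Annealed counts cannot exceed totals.")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- timecourse |>
    mutate(
      fraction = .data$annealed / .data$total,
      conf_low = (.data$fraction + z^2 / (2 * .data$total) -
                    z * sqrt(.data$fraction * (1 - .data$fraction) /
                               .data$total +
                               z^2 / (4 * .data$total^2))) /
        (1 + z^2 / .data$total),
      conf_high = (.data$fraction + z^2 / (2 * .data$total) +
                     z * sqrt(.data$fraction * (1 - .data$fraction) /
                                .data$total +
                                z^2 / (4 * .data$total^2))) /
        (1 + z^2 / .data$total)
    )
  class(out) <- c("annealing_curve", setdiff(class(out),
                                             "annealing_timecourse"))
  out
}

#' Estimate the annealing rate from a fraction-versus-time curve
#'
#' Least-squares fit of the single-exponential approach to completion
#' `f(t) = 1 - exp(-k t)`. Because the snapshots count the same molecules
#' cumulatively, the points are strongly correlated and the naive fit
#' covariance understates the sampling error; when the molecule totals are
#' known the standard error is therefore taken from a parametric bootstrap
#' of whole fields (seeded deterministically from the data, so results are
#' reproducible). An initial-slope estimate (`fraction/time` over the
#' earliest informative snapshots) is reported alongside as a cross-check.
#' Degenerate curves (all zero or all complete) yield a flagged result
#' instead of an error.
#'
#' @param curve An [annealing_fraction_curve()] result or any tibble with
#'   `time_s` and `fraction` (counts are converted automatically).
#' @param n_boot Parametric bootstrap replicates for the standard error
#'   (used when a `total` column is present; 0 falls back to the fit
#'   covariance).
#' @return Object of class `anneal_fit`: `rate` (s^-1), `se`, `rate_initial`
#'   (initial-slope estimate), `degenerate`, `n`; supports [tidy()] and
#'   [glance()].
#' @examples
#' cv <- tibble::tibble(time_s = c(0, 50, 100, 200, 400),
#'                      fraction = 1 - exp(-0.01 * time_s))
#' estimate_annealing_rate(cv)$rate
#' @export
estimate_annealing_rate <- function(curve, n_boot = 100L) {
  if (!"fraction" %in% names(curve) &&
      all(c("annealed", "total") %in% names(curve))) {
    curve <- annealing_fraction_curve(curve)
  }
  if (!all(c("time_s", "fraction") %in% names(curve))) {
    abort("`curve` needs columns time_s and fraction.")
  }
  if (nrow(curve) < 3L) abort("At least 3 snapshots are required.")
  t <- curve$time_s; f <- curve$fraction
  informative <- any(f > 0 & f < 1) || (any(f == 0) && any(f == 1))
  if (all(f == 0)) {
    return(structure(list(rate = 0, se = NA_real_,
                          rate_initial = 0, degenerate = TRUE,
                          n = length(t), data = curve, fit = NULL),
                     class = "anneal_fit"))
  }
  if (all(f >= 1) || !informative) {
    return(structure(list(rate = NA_real_, se = NA_real_,
                          rate_initial = NA_real_, degenerate = TRUE,
                          n = length(t), data = curve, fit = NULL),
                     class = "anneal_fit"))
  }
  fb <- mean(pmin(f[t > 0], 0.999))
  k0 <- -log(1 - fb) / mean(t[t > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ 1 - exp(-k * t), start = list(k = max(k0, 1e-8)),
                      lower = c(k = 0)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(rate = NA_real_, se = NA_real_,
                          rate_initial = k0, degenerate = TRUE,
                          n = length(t), data = curve, fit = NULL),
                     class = "anneal_fit"))
  }
  co <- summary(fit)$coefficients
  rate <- unname(co["k", "Estimate"])
  se <- unname(co["k", "Std. Error"])
  if (n_boot > 0 && "total" %in% names(curve)) {
    ntot <- round(stats::median(curve$total))
    boot_seed <- as.integer((sum(curve$fraction * 1e6) + ntot) %%
                              2147483629)
    ks <- withr::with_seed(boot_seed, vapply(seq_len(n_boot), function(i) {
      tt <- stats::rexp(ntot, rate)
      fb <- vapply(t, function(s) sum(tt <= s), numeric(1)) / ntot
      fit_b <- tryCatch(
        minpack.lm::nlsLM(fb ~ 1 - exp(-k * t),
                          start = list(k = rate), lower = c(k = 0)),
        error = function(e) NULL)
      if (is.null(fit_b)) NA_real_ else stats::coef(fit_b)[["k"]]
    }, numeric(1)))
    if (sum(is.finite(ks)) >= 10) se <- stats::sd(ks, na.rm = TRUE)
  }
  early <- which(t > 0 & f < 0.5)
  rate_initial <- if (length(early)) {
    mean(f[early] / t[early])
  } else k0
  structure(list(
    rate = rate, se = se,
    rate_initial = rate_initial,
    degenerate = FALSE, n = length(t), data = curve, fit = fit
  ), class = "anneal_fit")
}

#' Annealing enhancement factor (unwinding- vs binding-induced)
#'
#' Ratio of the annealing rate with ATP (unwinding-induced) to the rate
#' without ATP (binding-induced), with the standard error propagated from
#' both fits. Undefined when the binding-induced rate is zero.
#'
#' @param rate_with_atp,rate_without_atp [estimate_annealing_rate()] results,
#'   or numbers (optionally with `se` supplied via a `list(rate=, se=)`).
#' @return Tibble: `factor`, `se`, `conf_low`, `conf_high`.
#' @examples
#' enhancement_factor(list(rate = 0.01, se = 0.001),
#'                    list(rate = 0.002, se = 3e-4))
#' @export
enhancement_factor <- function(rate_with_atp, rate_without_atp) {
  get_rs <- function(x) {
    if (inherits(x, "anneal_fit")) c(x$rate, x$se)
    else if (is.list(x)) c(x$rate, x$se %||% NA_real_)
    else c(as.numeric(x), NA_real_)
  }
  a <- get_rs(rate_with_atp); b <- get_rs(rate_without_atp)
  if (!is.finite(b[1]) || b[1] <= 0) {
    abort("Binding-induced (no-ATP) rate is zero; enhancement factor undefined.")
  }
  fac <- a[1] / b[1]
  rel <- sqrt(sum(c(if (is.finite(a[2])) (a[2] / a[1])^2 else 0,
                    if (is.finite(b[2])) (b[2] / b[1])^2 else 0)))
  se <- fac * rel
  tibble(factor = fac, se = se,
         conf_low = fac - 1.96 * se, conf_high = fac + 1.96 * se)
}
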