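# Exponential-MLE rate from uncensored dwells; delta-method SEM rate/sqrt(n).
rate_from_dwells <- function(dwell_s, censored = NULL, sem_method = "delta",
                             n_boot = 1000L) {
  censored <- censored %||% rep(FALSE, length(dwell_s))
  use <- dwell_s[!censored]
  n <- length(use)
  if (n < 1L) return(NULL)
  rate <- 1 / mean(use)
  sem <- if (identical(sem_method, "bootstrap") && n > 1L) {
    stats::sd(vapply(seq_len(n_boot), function(i) {
      1 / mean(sample(use, n, replace = TRUE))
    }, numeric(1)))
  } else {
    rate / sqrt(n)
  }
  tibble(rate = rate, sem = sem, n = n, n_censored = sum(censored))
}

#' Estimate substep rates from dwell times
#'
#' For an exponential dwell the maximum-likelihood rate is the reciprocal
#' mean dwell; its SEM follows from the delta method as `rate / sqrt(n)`
#' (a seeded bootstrap is available). Censored dwells -- those cut short by
#' dissociation, photobleaching, strand separation or the end of the trace
#' -- are excluded from the mean and reported in `n_censored`.
#'
#' @param dwells A dwell tibble (e.g. from [extract_dwells()]) with columns
#'   `dwell_s` and optionally `censored` and `substep`, or a bare numeric
#'   vector of dwell times.
#' @param ... Additional grouping columns (tidy-select), e.g. `condition`;
#'   `substep` is always used when present.
#' @param sem_method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples.
#' @return Tibble with the grouping columns plus `rate` (s^-1), `sem`, `n`,
#'   `n_censored`.
#' @examples
#' estimate_rate(c(2, 2, 2))
#' @export
estimate_rate <- function(dwells, ..., sem_method = c("delta", "bootstrap"),
                          n_boot = 1000L) {
  sem_method <- match.arg(sem_method)
  if (is.numeric(dwells)) {
    dwells <- tibble(dwell_s = as.numeric(dwells))
  }
  if (!is.data.frame(dwells) || nrow(dwells) == 0L) {
    abort("`dwells` must be a non-empty dwell table or numeric vector.")
  }
  extra <- names(tidyselect::eval_select(rlang::expr(c(...)), dwells))
  keys <- unique(c(intersect("substep", names(dwells)), extra))
  if (!"censored" %in% names(dwells)) dwells$censored <- FALSE
  chk <- dwells |>
    summarise(any_unc = any(!.data$censored), .by = all_of(keys))
  if (!all(chk$any_unc)) {
    bad <- chk[!chk$any_unc, keys, drop = FALSE]
    lbl <- if (ncol(bad)) {
      paste0(" for ", paste(apply(bad, 1, paste, collapse = "/"),
                            collapse = ", "))
    } else ""
    abort(paste0("All dwells are censored", lbl,
                 "; no rate can be estimated."))
  }
  dwells |>
    reframe(rate_from_dwells(.data$dwell_s, .data$censored,
                             sem_method, n_boot),
            .by = all_of(keys))
}

#' Estimate the dissociation (off) rate from total bound times
#'
#' The off rate is the reciprocal mean total bound time over events whose
#' bound period ended in an observed dissociation; events censored by signal
#' loss or trace end are excluded and counted.
#'
#' @param events An [event_summary()] tibble (columns `total_bound_s`,
#'   `bound_censored`) or a numeric vector of bound times.
#' @param ... Grouping columns (tidy-select), e.g. `condition`.
#' @inheritParams estimate_rate
#' @return Tibble with `rate` (s^-1), `sem`, `n`, `n_censored` per group.
#' @examples
#' estimate_off_rate(c(10, 10))
#' @export
estimate_off_rate <- function(events, ...,
                              sem_method = c("delta", "bootstrap"),
                              n_boot = 1000L) {
  sem_method <- match.arg(sem_method)
  if (is.numeric(events)) {
    events <- tibble(total_bound_s = as.numeric(events),
                     bound_censored = FALSE)
  }
  if (!is.data.frame(events) || nrow(events) == 0L) {
    abort("`events` must be a non-empty event summary or numeric vector.")
  }
  if (!"bound_censored" %in% names(events)) events$bound_censored <- FALSE
  extra <- names(tidyselect::eval_select(rlang::expr(c(...)), events))
  chk <- events |>
    summarise(any_unc = any(!.data$bound_censored), .by = all_of(extra))
  if (!all(chk$any_unc)) {
    abort("All bound times are censored; no off rate can be estimated.")
  }
  events |>
    reframe(rate_from_dwells(.data$total_bound_s, .data$bound_censored,
                             sem_method, n_boot),
            .by = all_of(extra))
}

#' Fit the association constant from binding rates vs protein concentration
#'
#' Weighted least squares of binding rate against protein concentration with
#' the intercept fixed at zero by default (a binding rate must vanish at zero
#' protein); the slope is the association rate constant k_on in M^-1 s^-1.
#'
#' @param data Tibble with one row per concentration.
#' @param conc_col,rate_col,sem_col Column names (strings) for concentration
#'   (molar), rate (s^-1) and optional per-point SEM used for
#'   inverse-variance weights.
#' @param intercept Fit a free intercept instead (diagnostic mode).
#' @return An object of class `assoc_fit` with `slope`, `slope_se`,
#'   `intercept`, `r_squared`, `n` and the underlying `lm` fit; supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' d <- tibble::tibble(conc = c(10, 20, 40, 80) * 1e-9,
#'                     rate = 2.61e6 * conc)
#' fit_association_constant(d, conc_col = "conc", rate_col = "rate")
#' @export
fit_association_constant <- function(data, conc_col = "rha_conc",
                                     rate_col = "rate", sem_col = NULL,
                                     intercept = FALSE) {
  x <- data[[conc_col]]; y <- data[[rate_col]]
  if (length(unique(x)) < 2L) {
    abort("At least two distinct concentrations are required.")
  }
  w <- if (!is.null(sem_col) && sem_col %in% names(data) &&
           all(is.finite(data[[sem_col]])) && all(data[[sem_col]] > 0)) {
    1 / data[[sem_col]]^2
  } else rep(1, length(x))
  fit <- if (intercept) stats::lm(y ~ x, weights = w) else
    stats::lm(y ~ 0 + x, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  slope_row <- if (intercept) "x" else "x"
  structure(list(
    slope = unname(co[slope_row, "Estimate"]),
    slope_se = unname(co[slope_row, "Std. Error"]),
    intercept = if (intercept) unname(co["(Intercept)", "Estimate"]) else 0,
    r_squared = sm$r.squared,
    n = length(x),
    data = tibble(conc = x, rate = y, weight = w),
    fit = fit
  ), class = "assoc_fit")
}

#' Fit a Michaelis-Menten curve to unwinding rates vs ATP
#'
#' Nonlinear least squares of `v = Vmax * x / (Km + x)` (Levenberg-
#' Marquardt), with starting values Vmax = max rate and Km = the
#' concentration nearest half-maximal rate, and optional inverse-variance
#' weights. Non-convergence is reported through the `converged` flag rather
#' than silent numbers.
#'
#' @param data Tibble with one row per ATP concentration.
#' @param conc_col,rate_col,sem_col Column names for ATP concentration
#'   (molar), rate (s^-1) and optional per-point SEM.
#' @return An object of class `mm_fit` with `vmax`, `km`, their standard
#'   errors, `converged` and the `nls` fit; supports [tidy()], [glance()]
#'   and [autoplot()].
#' @examples
#' x <- c(10, 25, 50, 100, 250, 500, 1000) * 1e-6
#' fit_michaelis_menten(tibble::tibble(atp = x, rate = 1 * x / (26e-6 + x)),
#'                      conc_col = "atp", rate_col = "rate")
#' @export
fit_michaelis_menten <- function(data, conc_col = "atp_conc",
                                 rate_col = "rate", sem_col = NULL) {
  x <- data[[conc_col]]; y <- data[[rate_col]]
  if (length(unique(x)) < 3L) {
    abort("At least three distinct ATP concentrations are required.")
  }
  w <- if (!is.null(sem_col) && sem_col %in% names(data) &&
           all(is.finite(data[[sem_col]])) && all(data[[sem_col]] > 0)) {
    1 / data[[sem_col]]^2
  } else rep(1, length(x))
  vmax0 <- max(y)
  km0 <- x[which.min(abs(y - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(x)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ vmax * x / (km + x),
                      start = list(vmax = vmax0, km = km0),
                      weights = w,
                      lower = c(vmax = 0, km = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(vmax = NA_real_, km = NA_real_,
                          vmax_se = NA_real_, km_se = NA_real_,
                          converged = FALSE, n = length(x),
                          data = tibble(conc = x, rate = y, weight = w),
                          fit = NULL), class = "mm_fit"))
  }
  co <- summary(fit)$coefficients
  structure(list(
    vmax = unname(co["vmax", "Estimate"]),
    km = unname(co["km", "Estimate"]),
    vmax_se = unname(co["vmax", "Std. Error"]),
    km_se = unname(co["km", "Std. Error"]),
    converged = isTRUE(fit$convInfo$isConv),
    n = length(x),
    data = tibble(conc = x, rate = y, weight = w),
    fit = fit
  ), class = "mm_fit")
}

#' Per-substep rate ratios between two conditions
#'
#' Matches substep labels between a reference and a test rate table (e.g.
#' room temperature vs 37C) and returns the ratio test/reference with a
#' propagated standard error and normal 95% confidence interval.
#'
#' @param rates_reference,rates_test Rate tibbles from [estimate_rate()]
#'   (columns `substep`, `rate`, `sem`).
#' @return Tibble: `substep`, `ratio`, `se`, `conf_low`, `conf_high`.
#' @export
fold_change <- function(rates_reference, rates_test) {
  need <- c("substep", "rate", "sem")
  if (!all(need %in% names(rates_reference)) ||
      !all(need %in% names(rates_test))) {
    abort("Both rate tables need columns substep, rate, sem.")
  }
  if (!setequal(rates_reference$substep, rates_test$substep)) {
    abort("Substep labels do not match between the two rate tables.")
  }
  inner_join(
    rates_reference |> select("substep", ref_rate = "rate", ref_sem = "sem"),
    rates_test |> select("substep", test_rate = "rate", test_sem = "sem"),
    by = "substep"
  ) |>
    mutate(
      ratio = .data$test_rate / .data$ref_rate,
      se = .data$ratio * sqrt((.data$test_sem / .data$test_rate)^2 +
                                (.data$ref_sem / .data$ref_rate)^2),
      conf_low = .data$ratio - 1.96 * .data$se,
      conf_high = .data$ratio + 1.96 * .data$se
    ) |>
    select("substep", "ratio", "se", "conf_low", "conf_high")
}

#' Fit a binding isotherm to fluorescence polarization data
#'
#' Fits `P(c) = P0 + (Pmax - P0) * c / (Kd + c)` by nonlinear least squares,
#' as used to extract the equilibrium dissociation constant from a
#' polarization titration. A flat titration leaves Kd unidentifiable; this
#' is flagged rather than reported as a number.
#'
#' @param data Tibble of the titration.
#' @param conc_col,pol_col Column names for protein concentration (molar)
#'   and polarization.
#' @return An object of class `isotherm_fit` with `kd`, `p0`, `pmax`, their
#'   standard errors, `converged` and `identifiable` flags; supports
#'   [tidy()] and [glance()].
#' @export
fit_binding_isotherm <- function(data, conc_col = "conc", pol_col = "pol") {
  x <- data[[conc_col]]; y <- data[[pol_col]]
  if (length(unique(x)) < 4L) {
    abort("At least four concentrations are required for an isotherm fit.")
  }
  p0 <- min(y); pmax0 <- max(y)
  half <- p0 + (pmax0 - p0) / 2
  kd0 <- x[which.min(abs(y - half))]
  if (kd0 <= 0) kd0 <- stats::median(x[x > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ p0 + (pmax - p0) * x / (kd + x),
                      start = list(p0 = p0, pmax = pmax0, kd = kd0),
                      lower = c(p0 = -Inf, pmax = -Inf, kd = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, p0 = NA_real_, pmax = NA_real_,
                          kd_se = NA_real_, converged = FALSE,
                          identifiable = FALSE, n = length(x),
                          data = tibble(conc = x, pol = y), fit = NULL),
                     class = "isotherm_fit"))
  }
  co <- summary(fit)$coefficients
  kd <- unname(co["kd", "Estimate"]); kd_se <- unname(co["kd", "Std. Error"])
  span <- unname(co["pmax", "Estimate"] - co["p0", "Estimate"])
  identifiable <- is.finite(kd_se) && kd > 0 && kd_se / kd < 1 &&
    abs(span) > 4 * stats::sd(resid(fit))
  structure(list(
    kd = kd, p0 = unname(co["p0", "Estimate"]),
    pmax = unname(co["pmax", "Estimate"]), kd_se = kd_se,
    converged = isTRUE(fit$convInfo$isConv),
    identifiable = identifiable, n = length(x),
    data = tibble(conc = x, pol = y), fit = fit
  ), class = "isotherm_fit")
}
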