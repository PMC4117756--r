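# broom-style tidiers for the fit objects.

#' @export
tidy.assoc_fit <- function(x, ...) {
  out <- tibble(term = "slope", estimate = x$slope, std.error = x$slope_se)
  if (x$intercept != 0) {
    out <- bind_rows(out, tibble(term = "intercept",
                                 estimate = x$intercept,
                                 std.error = NA_real_))
  }
  out
}

#' @export
glance.assoc_fit <- function(x, ...) {
  tibble(slope = x$slope, slope_se = x$slope_se, intercept = x$intercept,
         r.squared = x$r_squared, n = x$n)
}

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("vmax", "km"),
         estimate = c(x$vmax, x$km),
         std.error = c(x$vmax_se, x$km_se))
}

#' @export
glance.mm_fit <- function(x, ...) {
  tibble(vmax = x$vmax, km = x$km, vmax_se = x$vmax_se, km_se = x$km_se,
         converged = x$converged, n = x$n)
}

#' @export
tidy.isotherm_fit <- function(x, ...) {
  tibble(term = c("kd", "p0", "pmax"),
         estimate = c(x$kd, x$p0, x$pmax),
         std.error = c(x$kd_se, NA_real_, NA_real_))
}

#' @export
glance.isotherm_fit <- function(x, ...) {
  tibble(kd = x$kd, kd_se = x$kd_se, converged = x$converged,
         identifiable = x$identifiable, n = x$n)
}

#' @export
tidy.anneal_fit <- function(x, ...) {
  tibble(term = "rate", estimate = x$rate, std.error = x$se)
}

#' @export
glance.anneal_fit <- function(x, ...) {
  tibble(rate = x$rate, se = x$se, rate_initial = x$rate_initial,
         degenerate = x$degenerate, n = x$n)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Vmax = %.4g /s (SE %.2g), Km = %.4g M (SE %.2g), %s\n",
              x$vmax, x$vmax_se, x$km, x$km_se,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("<assoc_fit> k_on = %.4g /M/s (SE %.2g), R^2 = %.4f\n",
              x$slope, x$slope_se, x$r_squared))
  invisible(x)
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("<isotherm_fit> Kd = %.4g M (SE %.2g)%s\n", x$kd, x$kd_se,
              if (isTRUE(x$identifiable)) "" else " [Kd not identifiable]"))
  invisible(x)
}

#' @export
print.anneal_fit <- function(x, ...) {
  cat(sprintf("<anneal_fit> k = %.4g /s (SE %.2g)%s\n", x$rate, x$se,
              if (isTRUE(x$degenerate)) " [degenerate curve]" else ""))
  invisible(x)
}
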