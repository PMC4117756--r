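# ggplot2 displays for traces, histograms and fits.

#' Plot one molecule's total-intensity and FRET trajectories
#'
#' @param fret A [compute_fret()] result (or a raw trace tibble, which is
#'   converted first).
#' @param molecule Molecule id to show (default: the first).
#' @param segments Optional [segment_substeps()] annotation; substep
#'   intervals are shaded.
#' @return A ggplot object (two stacked facets: total intensity, FRET).
#' @export
plot_trace <- function(fret, molecule = NULL, segments = NULL) {
  if (!"E" %in% names(fret)) fret <- compute_fret(fret)
  molecule <- molecule %||% fret$molecule_id[1L]
  d <- fret |>
    filter(.data$molecule_id == molecule) |>
    transmute(.data$time_s, `Total intensity` = .data$total,
              FRET = .data$E_clamp) |>
    pivot_longer(-"time_s", names_to = "channel", values_to = "value") |>
    mutate(channel = factor(.data$channel,
                            levels = c("Total intensity", "FRET")))
  gg <- ggplot(d, aes(x = .data$time_s, y = .data$value)) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "Time (s)", y = NULL,
         title = paste("Molecule", molecule)) +
    theme_bw()
  if (!is.null(segments)) {
    seg <- segments |>
      filter(.data$molecule_id == molecule) |>
      mutate(channel = factor("FRET", levels = levels(d$channel)))
    if (nrow(seg)) {
      gg <- gg + geom_rect(
        data = seg,
        aes(xmin = .data$t_start, xmax = .data$t_end,
            ymin = -Inf, ymax = Inf, fill = .data$label),
        alpha = 0.15, inherit.aes = FALSE) +
        labs(fill = "Substep")
    }
  }
  gg + geom_step(linewidth = 0.3)
}

#' @export
autoplot.fret_histogram <- function(object, ...) {
  ggplot(object, aes(x = (.data$bin_left + .data$bin_right) / 2,
                     y = .data$prob)) +
    geom_col(width = object$bin_right[1] - object$bin_left[1],
             fill = "steelblue", colour = NA) +
    labs(x = "FRET", y = "Fraction of frames",
         title = sprintf("FRET histogram (%d molecules, first %d frames)",
                         attr(object, "n_molecules"),
                         attr(object, "n_frames"))) +
    theme_bw()
}

#' @export
autoplot.mm_fit <- function(object, ...) {
  d <- object$data
  gg <- ggplot(d, aes(x = .data$conc * 1e6, y = .data$rate)) +
    geom_point() +
    labs(x = "[ATP] (uM)", y = "Unwinding rate (1/s)",
         title = sprintf("Michaelis-Menten fit: Km = %.3g uM",
                         object$km * 1e6)) +
    theme_bw()
  if (!is.null(object$fit)) {
    grid <- tibble(conc = seq(0, max(d$conc), length.out = 200))
    grid$rate <- object$vmax * grid$conc / (object$km + grid$conc)
    gg <- gg + geom_line(data = grid, colour = "firebrick")
  }
  gg
}

#' @export
autoplot.assoc_fit <- function(object, ...) {
  d <- object$data
  ggplot(d, aes(x = .data$conc * 1e9, y = .data$rate)) +
    geom_point() +
    geom_abline(intercept = object$intercept,
                slope = object$slope * 1e-9, colour = "firebrick") +
    labs(x = "[RHA] (nM)", y = "Binding rate (1/s)",
         title = sprintf("Association constant: %.3g x 1e6 /M/s",
                         object$slope / 1e6)) +
    theme_bw()
}

#' Plot an annealing fraction curve with its exponential fit
#'
#' @param curve An [annealing_fraction_curve()] result.
#' @param fit Optional [estimate_annealing_rate()] result.
#' @return A ggplot object.
#' @export
plot_annealing <- function(curve, fit = NULL) {
  gg <- ggplot(curve, aes(x = .data$time_s, y = .data$fraction)) +
    geom_pointrange(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                    linewidth = 0.3, size = 0.3) +
    labs(x = "Time (s)", y = "Annealed fraction") +
    theme_bw()
  if (!is.null(fit) && is.finite(fit$rate)) {
    grid <- tibble(time_s = seq(0, max(curve$time_s), length.out = 200))
    grid$fraction <- 1 - exp(-fit$rate * grid$time_s)
    gg <- gg +
      geom_line(data = grid, colour = "firebrick") +
      labs(title = sprintf("Annealing rate %.3g /s", fit$rate))
  }
  gg
}
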