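# ggplot2 views of the main result types.

#' Plot an acquisition scheme
#'
#' b-value against diffusion time, coloured by gradient direction.
#'
#' @param scheme A scheme tibble.
#' @return A ggplot.
#' @export
plot_scheme <- function(scheme) {
  dat <- dplyr::mutate(scheme,
    direction = sprintf("[%.2g %.2g %.2g]", .data$nx, .data$ny, .data$nz)
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$Delta, y = .data$b, colour = .data$direction)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = expression(Delta ~ "(ms)"), y = expression(b ~ (s / mm^2)),
      colour = "direction"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an apparent-diffusivity trend over diffusion time
#'
#' @param adc Tibble from [apparent_dperp()] (columns `Delta`, `adc`),
#'   optionally with extra grouping columns mapped via `...`.
#' @param ... Extra aesthetics forwarded to `ggplot2::aes()`.
#' @return A ggplot.
#' @export
plot_dperp_trend <- function(adc, ...) {
  ggplot2::ggplot(
    adc,
    ggplot2::aes(x = .data$Delta, y = .data$adc, ...)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(Delta ~ "(ms)"),
      y = expression(D[perp] ~ (mu * m^2 / ms))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the intra/extra attenuation budget
#'
#' @param budget Tibble from [run_attenuation_budget()].
#' @return A ggplot of attenuation percentages against b, faceted by
#'   distribution and diffusivity.
#' @export
plot_attenuation_budget <- function(budget) {
  long <- tidyr::pivot_longer(budget, c("intra_pct", "extra_pct"),
    names_to = "compartment", values_to = "pct"
  )
  long$compartment <- sub("_pct", "-axonal", long$compartment)
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = factor(.data$b), y = .data$pct,
      fill = .data$compartment
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$D_f),
      cols = ggplot2::vars(.data$distribution)
    ) +
    ggplot2::labs(
      x = expression(b ~ (s / mm^2)),
      y = "signal attenuation (%)", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn pack_cylinders Plot the cylinder cross-sections of a
#'   substrate.
#' @param object,x An `axt_substrate`.
#' @param ... Unused.
#' @export
autoplot.axt_substrate <- function(object, ...) {
  cyl <- object$cylinders
  th <- seq(0, 2 * pi, length.out = 60)
  poly <- purrr::imap_dfr(seq_len(nrow(cyl)), function(i, ...) {
    tibble::tibble(
      id = i,
      y = cyl$y[i] + cyl$r[i] * cos(th),
      z = cyl$z[i] + cyl$r[i] * sin(th)
    )
  })
  ggplot2::ggplot(poly, ggplot2::aes(.data$y, .data$z, group = .data$id)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.6) +
    ggplot2::coord_fixed(xlim = c(0, object$box), ylim = c(0, object$box)) +
    ggplot2::labs(
      x = "y (um)", y = "z (um)",
      title = sprintf("area fraction %.3f", object$achieved_icvf)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn tidy.axt_fit Dot-and-whisker view of the estimates.
#' @param object An `axt_fit`.
#' @export
autoplot.axt_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$estimate - .data$std.error,
        ymax = .data$estimate + .data$std.error
      ),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal()
}

#' @describeIn run_density_bias_experiment Density estimates against
#'   diffusion time per condition and fit variant (the report's summary
#'   view); for Monte Carlo recovery reports, fitted against true diameter.
#' @param object An `axt_report`.
#' @param ... Unused.
#' @export
autoplot.axt_report <- function(object, ...) {
  if (object$kind == "density_bias") {
    d <- dplyr::mutate(object$summary,
      condition = sprintf(
        "f_r=%.2g, R=%.2g, D=%.2g",
        .data$f_r, .data$radius, .data$D_0
      )
    )
    ggplot2::ggplot(
      d,
      ggplot2::aes(.data$Delta, .data$mean_f_r, colour = .data$variant)
    ) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_hline(
        ggplot2::aes(yintercept = .data$f_r),
        linetype = 2
      ) +
      ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
      ggplot2::labs(
        x = expression(Delta ~ "(ms)"),
        y = "estimated axonal density"
      ) +
      ggplot2::theme_minimal()
  } else {
    d <- object$estimates
    ggplot2::ggplot(
      d,
      ggplot2::aes(
        x = factor(.data$mean_diameter), y = .data$diameter_hat,
        colour = .data$time_dependent
      )
    ) +
      ggplot2::geom_boxplot() +
      ggplot2::geom_point(
        ggplot2::aes(y = .data$mean_diameter),
        colour = "black", shape = 4, size = 3
      ) +
      ggplot2::facet_grid(
        rows = ggplot2::vars(.data$D_f),
        cols = ggplot2::vars(.data$snr)
      ) +
      ggplot2::labs(
        x = "true mean diameter (um)",
        y = "fitted mean diameter (um)",
        colour = "time-dependent"
      ) +
      ggplot2::theme_minimal()
  }
}
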