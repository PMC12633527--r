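# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-fascicle morphometrics
#' @param x A [measure_cross_section()] result.
#' @param ... Unused.
#' @return Per-fascicle tibble.
#' @export
tidy.morphometrics <- function(x, ...) x$fascicles

#' One-row nerve-level morphometrics summary
#' @param x A [measure_cross_section()] result.
#' @param ... Unused.
#' @export
glance.morphometrics <- function(x, ...) {
  tibble::tibble(
    nerve_effective_diameter_um = x$nerve_effective_diameter_um,
    fascicle_count = x$fascicle_count,
    mean_fascicle_diameter_um = mean(x$fascicles$effective_diameter_um),
    mean_perineurium_thickness_um = mean(x$fascicles$perineurium_thickness_um)
  )
}

#' Tidy split/merge events
#' @param x A [detect_split_merge()] report.
#' @param ... Unused.
#' @export
tidy.split_merge_report <- function(x, ...) x$events

#' One-row split/merge summary
#' @param x A [detect_split_merge()] report.
#' @param ... Unused.
#' @export
glance.split_merge_report <- function(x, ...) {
  tibble::tibble(n_events = nrow(x$events), rate_per_mm = x$rate_per_mm,
                 length_analyzed_mm = x$length_analyzed_mm)
}

#' Tidy a quadratic threshold fit
#' @param x A [fit_quadratic_thresholds()] result.
#' @param ... Unused.
#' @export
tidy.threshold_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "diameter", "diameter^2"),
                 estimate = c(x$c0, x$c1, x$c2))
}

#' Quadratic threshold fit summary
#' @param x A [fit_quadratic_thresholds()] result.
#' @param ... Unused.
#' @export
glance.threshold_fit <- function(x, ...) {
  tibble::tibble(n = length(x$diameters_um),
                 rms_residual = sqrt(mean(x$residuals^2)))
}

#' Tidy a threshold map
#' @param x An [assign_population_thresholds()] result.
#' @param ... Unused.
#' @export
tidy.threshold_map <- function(x, ...) x$fibers

#' Tidy a dose-response curve
#' @param x A [dose_response_curve()] result.
#' @param ... Unused.
#' @export
tidy.dose_response <- function(x, ...) x$curve

#' Plot a nerve cross section
#'
#' @param object A [cross_section()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cross_section <- function(object, ...) {
  poly_df <- function(p, id, what) {
    tibble::tibble(x = p[, 1], y = p[, 2], id = id, what = what)
  }
  df <- dplyr::bind_rows(c(
    list(poly_df(object$epineurium, "epineurium", "epineurium")),
    purrr::imap(object$fascicles, function(f, i)
      poly_df(f$outer, paste0("outer_", i), "perineurium")),
    purrr::imap(object$fascicles, function(f, i)
      poly_df(f$inner, paste0("inner_", i), "endoneurium"))
  ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$id, fill = .data$what)) +
    ggplot2::geom_polygon(color = "grey25", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c(epineurium = "#f2e6d9",
                                          perineurium = "#c8a2c8",
                                          endoneurium = "#f7f7c6")) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response (recruitment) curve
#'
#' @param object A [dose_response_curve()] result.
#' @param ... Unused.
#' @export
autoplot.dose_response <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$amplitude_mA,
                               y = .data$fraction_activated)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Amplitude (mA)", y = "Fraction of fibers activated") +
    ggplot2::theme_minimal()
}

#' Plot a fiber threshold heat map over the cross section
#'
#' @param object An [assign_population_thresholds()] result.
#' @param ... Unused.
#' @export
autoplot.threshold_map <- function(object, ...) {
  ggplot2::ggplot(object$fibers,
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               color = .data$threshold_mA,
                               size = .data$diameter_um)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::scale_color_viridis_c(name = "Threshold (mA)") +
    ggplot2::scale_size_continuous(name = "Diameter (µm)", range = c(0.3, 2.5)) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a centerline in the transverse plane and along z
#'
#' @param object An [extract_centerline()] result.
#' @param ... Unused.
#' @export
autoplot.centerline <- function(object, ...) {
  df <- tidyr::pivot_longer(object$points, c("x_um", "y_um"),
                            names_to = "axis", values_to = "position_um")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_um, y = .data$position_um,
                                   color = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (µm)", y = "centroid position (µm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
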