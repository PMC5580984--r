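#' Plot the gating hierarchy
#'
#' Two panels of the classic gating views: FSC-A x SSC-A (intact-cell box)
#' and FSC-A x FSC-H (singlet band), with events colored by the deepest
#' gate they survive. Axes stay on the linear acquisition scale, as scatter
#' gates are defined there.
#'
#' @param table The [event_table()] that was gated.
#' @param gating A `gating_result` from [apply_hierarchy()] or
#'   [gate_sample()].
#' @param max_points Subsample cap for plotting (default 20000).
#' @return A ggplot object.
#' @export
plot_gating <- function(table, gating, max_points = 20000) {
  stopifnot(inherits(gating, "gating_result"))
  stage <- dplyr::case_when(
    gating$masks$viable ~ "viable",
    gating$masks$intact ~ "intact (not viable)",
    gating$masks$singlet ~ "singlet (not intact)",
    TRUE ~ "excluded"
  )
  df <- tibble::tibble(
    fsc_a = role_values(table, "fsc_a"),
    fsc_h = role_values(table, "fsc_h"),
    ssc_a = role_values(table, "ssc_a"),
    stage = factor(stage, levels = c("excluded", "singlet (not intact)",
                                     "intact (not viable)", "viable"))
  )
  if (nrow(df) > max_points) {
    df <- dplyr::slice_sample(df, n = max_points)
  }
  long <- tidyr::pivot_longer(df, c("ssc_a", "fsc_h"),
                              names_to = "panel", values_to = "y")
  long$panel <- factor(long$panel, levels = c("ssc_a", "fsc_h"),
                       labels = c("SSC-A (intact gate)",
                                  "FSC-H (singlet gate)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fsc_a, y = .data$y,
                                     colour = .data$stage)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "FSC-A", y = NULL, colour = "gate") +
    ggplot2::theme_minimal()
}

#' @rdname plot_gating
#' @param object A `gating_result`.
#' @param ... Passed to [plot_gating()]; must include `table`.
#' @export
autoplot.gating_result <- function(object, ...) {
  plot_gating(gating = object, ...)
}

#' Quadrant plot of DNA uptake versus protein expression
#'
#' The two-readout dot plot: labeled-DNA channel against protein channel on
#' log10 display scales, with the positivity thresholds and quadrant
#' percentages drawn in. Display transforms affect only this plot; all
#' statistics are computed on linear values.
#'
#' @param sample Viable-gated [event_table()].
#' @param quad A `quadrant_stats` from [quadrant_stats()].
#' @param max_points Subsample cap for plotting.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(sample, quad, max_points = 20000) {
  stopifnot(inherits(quad, "quadrant_stats"))
  df <- tibble::tibble(
    x = pmax(role_values(sample, "dna_label"), 1),
    y = pmax(role_values(sample, "protein"), 1)
  )
  if (nrow(df) > max_points) df <- dplyr::slice_sample(df, n = max_points)
  tx <- max(quad$thresholds[["x"]], 1)
  ty <- max(quad$thresholds[["y"]], 1)
  lab <- tibble::tibble(
    quadrant = names(quad$pct),
    pct = unname(quad$pct),
    hx = c(Inf, Inf, -Inf, -Inf)[match(names(quad$pct),
                                       c("Q1", "Q2", "Q3", "Q4"))],
    hy = c(-Inf, Inf, Inf, -Inf)[match(names(quad$pct),
                                       c("Q1", "Q2", "Q3", "Q4"))]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = tx, linetype = 2) +
    ggplot2::geom_hline(yintercept = ty, linetype = 2) +
    ggplot2::geom_label(data = lab, ggplot2::aes(
      x = .data$hx, y = .data$hy,
      label = sprintf("%s: %.1f%%", .data$quadrant, .data$pct)),
      hjust = "inward", vjust = "inward", size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "labeled DNA fluorescence",
                  y = "protein fluorescence") +
    ggplot2::theme_minimal()
}

#' Plot an MESF standard curve
#'
#' Bead peaks and the fitted log-log regression of known MESF on peak MFI.
#'
#' @param object A `bead_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bead_calibration <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$peak_mfi, y = .data$known_mesf)) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::geom_point(size = 2, colour = "steelblue4") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "bead peak MFI (acquisition units)",
      y = "known MESF",
      title = sprintf("MESF standard curve (slope %.3f, r² %.4f)",
                      object$slope, object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot a transfection time course
#'
#' Blank-corrected DNA and protein signals against harvest time, each
#' scaled to its own maximum so the uptake pulse and expression rise share
#' one panel.
#'
#' @param tc Data frame with columns `timepoint_h`, `dmfi_dna`,
#'   `dmfi_protein`.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc) {
  tc <- tibble::as_tibble(tc)
  long <- tidyr::pivot_longer(
    dplyr::transmute(
      tc, timepoint_h = .data$timepoint_h,
      `labeled DNA` = .data$dmfi_dna / max(.data$dmfi_dna),
      protein = .data$dmfi_protein / max(.data$dmfi_protein)),
    -"timepoint_h", names_to = "readout", values_to = "relative")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint_h,
                                     y = .data$relative,
                                     colour = .data$readout)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "hours post transfection",
                  y = "dMFI (fraction of maximum)", colour = NULL) +
    ggplot2::theme_minimal()
}
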