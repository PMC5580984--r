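#' Gates and the gating hierarchy
#'
#' cytofect reproduces the standard manual gating sequence of a transfection
#' experiment as deterministic, parameterized gates: singlets (doublet
#' discrimination on the FSC-H/FSC-A pulse ratio), intact cells (a
#' percentile box on FSC-A x SSC-A that removes debris and gross outliers),
#' and viable cells (either a viability-dye threshold or a scatter-based
#' dead-cell region). A gate is a pure predicate over one event; fitting a
#' gate estimates its parameters from data, applying it evaluates the
#' predicate.
#'
#' All percentiles are computed with linear interpolation between order
#' statistics (`stats::quantile()` type 7), so gates are deterministic given
#' the table and parameters.
#'
#' @name gating
NULL

new_gate <- function(kind, params, channels) {
  structure(list(kind = kind, params = params, channels = channels),
            class = "cytofect_gate")
}

#' @export
print.cytofect_gate <- function(x, ...) {
  cat(sprintf("<cytofect gate: %s on %s>\n", x$kind,
              paste(x$channels, collapse = ", ")))
  cat(paste0("  ", names(x$params), " = ",
             signif(unlist(x$params), 6), collapse = "\n"), "\n")
  invisible(x)
}

pctile <- function(x, p) {
  unname(stats::quantile(x, p / 100, type = 7, names = FALSE))
}

#' Fit a singlet (doublet-discrimination) gate
#'
#' Doublets are two cells measured as one event: their pulse area roughly
#' doubles while the height does not, so the FSC-H/FSC-A ratio drops well
#' below that of single cells. The gate keeps events whose ratio lies within
#' a symmetric band around the population median ratio.
#'
#' @param table An [event_table()] with `fsc_a` and `fsc_h` roles.
#' @param band_width Half-width of the ratio band as a fraction of the
#'   median ratio (default 0.15): events with
#'   `fsc_h/fsc_a` in `[m*(1-w), m*(1+w)]` pass, where `m` is the median
#'   ratio over events with positive FSC-A.
#' @return A `ratio_band` gate.
#' @export
fit_singlet_gate <- function(table, band_width = 0.15) {
  if (n_events(table) < 50) {
    abort_insufficient("need at least 50 events to fit a singlet gate")
  }
  fsc_a <- role_values(table, "fsc_a")
  if (mean(fsc_a > 0) < 0.9) {
    abort_data("singlet gate requires positive FSC-A for at least 90% of events")
  }
  fsc_h <- role_values(table, "fsc_h")
  ok <- fsc_a > 0
  m <- stats::median(fsc_h[ok] / fsc_a[ok])
  new_gate("ratio_band",
           list(center = m, width = band_width),
           c("fsc_h", "fsc_a"))
}

#' Fit an intact-cell gate
#'
#' A percentile box on FSC-A and SSC-A that removes debris (far-low scatter)
#' and gross outliers. Percentiles are taken per axis on a reference table
#' when given (normally a clean untransfected control, because transfection
#' perturbs scatter), otherwise on the sample itself.
#'
#' @param table An [event_table()].
#' @param lower_pct,upper_pct Per-axis percentile bounds (defaults 2 and
#'   99.5).
#' @param reference Optional reference [event_table()] on which the
#'   percentiles are computed.
#' @return A `percentile_box` gate. A degenerate axis (zero spread) passes
#'   all events on that axis, with a warning.
#' @export
fit_intact_gate <- function(table, lower_pct = 2, upper_pct = 99.5,
                            reference = NULL) {
  ref <- if (is.null(reference)) table else reference
  if (n_events(ref) < 50) {
    abort_insufficient("need at least 50 events to fit an intact-cell gate")
  }
  box <- list()
  for (role in c("fsc_a", "ssc_a")) {
    x <- role_values(ref, role)
    lo <- pctile(x, lower_pct)
    hi <- pctile(x, upper_pct)
    if (hi <= lo) {
      warn_cytofect(paste0("degenerate ", role,
                           " axis in intact gate; axis passes all events"))
      lo <- -Inf; hi <- Inf
    }
    box[[paste0(role, "_lo")]] <- lo
    box[[paste0(role, "_hi")]] <- hi
  }
  new_gate("percentile_box", box, c("fsc_a", "ssc_a"))
}

#' Fit a viability gate from a dead-cell dye
#'
#' Dead and dying cells take up the viability dye; the gate thresholds the
#' dye channel at a high percentile of an untransfected control so that, by
#' construction, at most `100 - pct` percent of control events are called
#' dead. Events strictly above the threshold are dead.
#'
#' @param table An [event_table()] with a `viability` role (the sample; used
#'   only to validate channels).
#' @param dye_control Control [event_table()] supplying the threshold.
#' @param pct Control percentile for the threshold (default 99.5).
#' @return A `threshold_above` gate (above = dead).
#' @export
viability_gate_dye <- function(table, dye_control, pct = 99.5) {
  if (!has_role(table, "viability") || !has_role(dye_control, "viability")) {
    abort_config("viability role must be mapped in both sample and control")
  }
  if (n_events(dye_control) == 0) {
    abort_insufficient("empty dye control")
  }
  thr <- pctile(role_values(dye_control, "viability"), pct)
  new_gate("threshold_above", list(threshold = thr, pct = pct), "viability")
}

#' Fit a scatter-based viability gate
#'
#' When a dye cannot be used (electroporation experiments exclude dye-based
#' viability), dead cells are identified from scatter alone: they shrink
#' (low FSC-A) and become more granular (high SSC-A). The dead region is the
#' joint tail `FSC-A < reference low percentile` and `SSC-A > reference high
#' percentile`, with percentiles from an untransfected reference.
#'
#' @param table An [event_table()] (the sample; used only to validate
#'   channels).
#' @param reference Untransfected reference [event_table()].
#' @param low_pct FSC-A percentile below which cells look shrunken
#'   (default 10).
#' @param high_pct SSC-A percentile above which cells look granular
#'   (default 75).
#' @return A `percentile_box` complement gate (inside the corner = dead).
#' @export
viability_gate_scatter <- function(table, reference, low_pct = 10,
                                   high_pct = 75) {
  if (n_events(reference) < 50) {
    abort_insufficient("need at least 50 reference events for scatter viability")
  }
  fsc_lo <- pctile(role_values(reference, "fsc_a"), low_pct)
  ssc_hi <- pctile(role_values(reference, "ssc_a"), high_pct)
  new_gate("scatter_dead_corner",
           list(fsc_below = fsc_lo, ssc_above = ssc_hi,
                low_pct = low_pct, high_pct = high_pct),
           c("fsc_a", "ssc_a"))
}

#' Evaluate a gate predicate on every event
#'
#' @param gate A fitted gate.
#' @param table An [event_table()].
#' @return Logical vector, `TRUE` where the event passes (for viability
#'   gates: `TRUE` = viable).
#' @export
gate_pass <- function(gate, table) {
  stopifnot(inherits(gate, "cytofect_gate"))
  switch(gate$kind,
    ratio_band = {
      a <- role_values(table, "fsc_a")
      h <- role_values(table, "fsc_h")
      m <- gate$params$center
      w <- gate$params$width
      r <- ifelse(a > 0, h / a, NA_real_)
      !is.na(r) & r >= m * (1 - w) & r <= m * (1 + w)
    },
    percentile_box = {
      a <- role_values(table, "fsc_a")
      s <- role_values(table, "ssc_a")
      a >= gate$params$fsc_a_lo & a <= gate$params$fsc_a_hi &
        s >= gate$params$ssc_a_lo & s <= gate$params$ssc_a_hi
    },
    threshold_above = {
      v <- role_values(table, "viability")
      v <= gate$params$threshold   # above threshold = dead
    },
    scatter_dead_corner = {
      a <- role_values(table, "fsc_a")
      s <- role_values(table, "ssc_a")
      !(a < gate$params$fsc_below & s > gate$params$ssc_above)
    },
    abort_config(paste0("unknown gate kind: ", gate$kind))
  )
}

#' Apply the gating hierarchy
#'
#' Applies singlet, intact and (optionally) viability gates in order; each
#' stage is evaluated within the previous stage's survivors, so the masks
#' are nested: viable implies intact implies singlet.
#'
#' @param table An [event_table()].
#' @param singlet_gate,intact_gate Fitted gates (see [fit_singlet_gate()],
#'   [fit_intact_gate()]).
#' @param viability_gate Optional viability gate; when `NULL`, the viable
#'   mask equals the intact mask.
#' @return A `gating_result`: full-length logical masks (`singlet`,
#'   `intact`, `viable`), stage counts, stage-wise survival fractions (`NA`
#'   when the previous stage is empty), and the gates used.
#' @export
apply_hierarchy <- function(table, singlet_gate, intact_gate,
                            viability_gate = NULL) {
  n <- n_events(table)
  if (n == 0) {
    masks <- tibble::tibble(singlet = logical(0), intact = logical(0),
                            viable = logical(0))
    counts <- c(total = 0L, singlet = 0L, intact = 0L, viable = 0L)
    fractions <- c(singlet = NA_real_, intact = NA_real_, viable = NA_real_)
  } else {
    singlet <- gate_pass(singlet_gate, table)
    intact <- singlet & gate_pass(intact_gate, table)
    viable <- if (is.null(viability_gate)) intact else {
      intact & gate_pass(viability_gate, table)
    }
    masks <- tibble::tibble(singlet = singlet, intact = intact,
                            viable = viable)
    counts <- c(total = n, singlet = sum(singlet), intact = sum(intact),
                viable = sum(viable))
    frac <- function(num, den) if (den == 0) NA_real_ else num / den
    fractions <- c(singlet = frac(counts[["singlet"]], n),
                   intact = frac(counts[["intact"]], counts[["singlet"]]),
                   viable = frac(counts[["viable"]], counts[["intact"]]))
  }
  structure(list(masks = masks, counts = counts, fractions = fractions,
                 gates = list(singlet = singlet_gate, intact = intact_gate,
                              viability = viability_gate)),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat("<cytofect gating result>\n")
  cat(sprintf("  events: %d; singlet %d; intact %d; viable %d\n",
              x$counts[["total"]], x$counts[["singlet"]],
              x$counts[["intact"]], x$counts[["viable"]]))
  invisible(x)
}

#' Fit and apply the standard gating chain for one sample
#'
#' Convenience wrapper used throughout the pipeline: fits the singlet gate
#' on the sample, the intact gate against a reference (untransfected
#' control) when given, and the viability gate by dye when a viability
#' channel is mapped, otherwise by scatter when a reference is available
#' (the automatic fallback for electroporation samples, where viability
#' dyes cannot be used).
#'
#' @param table Sample [event_table()].
#' @param reference Optional untransfected reference table.
#' @param params List of gate parameters overriding the defaults:
#'   `band_width`, `intact_lower_pct`, `intact_upper_pct`, `dye_pct`,
#'   `scatter_low_pct`, `scatter_high_pct`, `viability` (`"auto"`, `"dye"`,
#'   `"scatter"`, or `"none"`).
#' @return A `gating_result`.
#' @export
gate_sample <- function(table, reference = NULL, params = list()) {
  p <- utils::modifyList(default_gate_params(), params)
  sg <- fit_singlet_gate(table, band_width = p$band_width)
  ig <- fit_intact_gate(table, lower_pct = p$intact_lower_pct,
                        upper_pct = p$intact_upper_pct,
                        reference = reference)
  method <- p$viability
  if (method == "auto") {
    method <- if (has_role(table, "viability")) "dye"
              else if (!is.null(reference)) "scatter" else "none"
  }
  vg <- switch(method,
    dye = {
      ctrl <- if (!is.null(reference) && has_role(reference, "viability")) {
        reference
      } else {
        table
      }
      viability_gate_dye(table, ctrl, pct = p$dye_pct)
    },
    scatter = viability_gate_scatter(
      table, if (is.null(reference)) table else reference,
      low_pct = p$scatter_low_pct, high_pct = p$scatter_high_pct),
    none = NULL
  )
  res <- apply_hierarchy(table, sg, ig, vg)
  res$viability_method <- method
  res
}

#' Default gate parameters
#'
#' @return Named list of the tunable gating defaults.
#' @export
default_gate_params <- function() {
  list(band_width = 0.15,
       intact_lower_pct = 2,
       intact_upper_pct = 99.5,
       dye_pct = 99.5,
       scatter_low_pct = 10,
       scatter_high_pct = 75,
       viability = "auto")
}

viable_events <- function(table, gating) {
  filter_events(table, gating$masks$viable)
}
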