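#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a transfection readout into a one-row tibble
#'
#' @param x A `transfection_readout`.
#' @param ... Unused.
#' @return One-row tibble with the percentage, dMFI, MESF and copy-number
#'   fields plus thresholds and gate survival fractions.
#' @export
tidy.transfection_readout <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    timepoint_h = if (is.null(x$timepoint_h)) NA_real_ else x$timepoint_h,
    pct_dna_pos = x$pct_dna_pos,
    pct_protein_pos = x$pct_protein_pos,
    dmfi_dna = x$dmfi_dna,
    dmfi_protein = x$dmfi_protein,
    mesf_dna = x$mesf_dna,
    mesf_protein = x$mesf_protein,
    plasmid_copies_per_cell = x$plasmid_copies_per_cell,
    plasmid_moles_per_cell = x$plasmid_moles_per_cell,
    n_viable = x$n_viable,
    threshold_dna = unname(x$thresholds[["x_dna_label"]]),
    threshold_protein = unname(x$thresholds[["y_protein"]]),
    q1 = unname(x$quadrants$pct[["Q1"]]),
    q2 = unname(x$quadrants$pct[["Q2"]]),
    q3 = unname(x$quadrants$pct[["Q3"]]),
    q4 = unname(x$quadrants$pct[["Q4"]]),
    frac_singlet = unname(x$gating$fractions[["singlet"]]),
    frac_intact = unname(x$gating$fractions[["intact"]]),
    frac_viable = unname(x$gating$fractions[["viable"]]),
    viability_method = x$viability_method,
    # fitted gate geometry, serialized for auditability
    gate_singlet_ratio = x$gating$gates$singlet$params$center,
    gate_fsc_lo = x$gating$gates$intact$params$fsc_a_lo,
    gate_fsc_hi = x$gating$gates$intact$params$fsc_a_hi,
    gate_ssc_lo = x$gating$gates$intact$params$ssc_a_lo,
    gate_ssc_hi = x$gating$gates$intact$params$ssc_a_hi,
    gate_viability_threshold = if (is.null(x$gating$gates$viability) ||
                                   is.null(x$gating$gates$viability$params$threshold))
      NA_real_ else x$gating$gates$viability$params$threshold
  )
}

#' Tidy a toxicity readout
#'
#' @param x A `toxicity_readout`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.toxicity_readout <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    pct_dead = x$pct_dead,
    pct_dead_control = x$pct_dead_control,
    excess_death = x$excess_death,
    pct_dead_among_dna_pos = x$pct_dead_among_dna_pos,
    toxicity_method = x$method
  )
}

#' Tidy a gating result into a per-stage table
#'
#' @param x A `gating_result`.
#' @param ... Unused.
#' @return Tibble with stage, events surviving, and stage-wise survival
#'   fraction.
#' @export
tidy.gating_result <- function(x, ...) {
  tibble::tibble(
    stage = c("total", "singlet", "intact", "viable"),
    n = unname(x$counts),
    fraction = c(NA_real_, unname(x$fractions))
  )
}

#' Tidy a quadrant table
#'
#' @param x A `quadrant_stats`.
#' @param ... Unused.
#' @return Tibble with quadrant and percentage.
#' @export
tidy.quadrant_stats <- function(x, ...) {
  tibble::tibble(quadrant = names(x$pct), pct = unname(x$pct))
}

#' Tidy a bead calibration into a per-peak table
#'
#' @param x A `bead_calibration`.
#' @param ... Unused.
#' @return Tibble with peak MFI, known MESF, fitted MESF and the relative
#'   round-trip error of each peak.
#' @export
tidy.bead_calibration <- function(x, ...) {
  fitted <- 10^(x$intercept + x$slope * log10(x$peak_mfi))
  tibble::tibble(
    peak = seq_along(x$peak_mfi),
    peak_mfi = x$peak_mfi,
    known_mesf = x$known_mesf,
    fitted_mesf = fitted,
    rel_error = fitted / x$known_mesf - 1
  )
}

#' One-row summary of a bead calibration
#'
#' @param x A `bead_calibration`.
#' @param ... Unused.
#' @return Tibble with slope, intercept, r2, number of peaks and the valid
#'   MFI range.
#' @export
glance.bead_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r2 = x$r2,
    n_peaks = length(x$peak_mfi),
    mfi_min = x$valid_range[1], mfi_max = x$valid_range[2]
  )
}
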