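#' Control set
#'
#' The three negative controls that anchor the assay:
#' * `untransfected` - untransfected cells; reference for scatter gating,
#'   viability thresholds and toxicity comparison.
#' * `unlabeled_plasmid` - cells transfected with unlabeled plasmid,
#'   harvested when protein can be quantified; background for the labeled-DNA
#'   (FITC) channel, both for the positivity threshold and the blank
#'   correction.
#' * `zero_timepoint` - cells harvested before any protein is expressed;
#'   background for the protein channel. May be the same physical sample as
#'   the unlabeled-plasmid control acquired at t = 0.
#'
#' @param untransfected,unlabeled_plasmid,zero_timepoint [event_table()]s
#'   sharing the sample's channel roles.
#' @return A `control_set`.
#' @export
control_set <- function(untransfected, unlabeled_plasmid, zero_timepoint) {
  for (tb in list(untransfected, unlabeled_plasmid, zero_timepoint)) {
    if (!inherits(tb, "event_tbl")) {
      abort_config("all controls must be event tables")
    }
  }
  structure(list(untransfected = untransfected,
                 unlabeled_plasmid = unlabeled_plasmid,
                 zero_timepoint = zero_timepoint),
            class = "control_set")
}

#' Positivity threshold from a negative control
#'
#' The threshold above which an event counts as positive on a channel: a
#' high percentile (default 99.9) of the viable-gated negative control, so
#' that at most 0.1% of control events exceed it by construction.
#' Percentiles use linear interpolation between order statistics.
#'
#' @param control Viable-gated control [event_table()].
#' @param role Channel role (`"dna_label"` or `"protein"`).
#' @param pct Control percentile (default 99.9).
#' @return The threshold (acquisition-scale units).
#' @export
positivity_threshold <- function(control, role, pct = 99.9) {
  if (n_events(control) == 0) {
    abort_insufficient("empty control: cannot compute positivity threshold")
  }
  if (n_events(control) < 200) {
    warn_cytofect(sprintf(
      "only %d viable control events; positivity threshold is unstable",
      n_events(control)))
  }
  pctile(role_values(control, role), pct)
}

#' Quadrant statistics on the DNA x protein plane
#'
#' Partitions viable events by one threshold per axis (x = labeled-DNA
#' channel, y = protein channel). Quadrants follow the usual convention:
#' Q1 = x+/y-, Q2 = x+/y+, Q3 = x-/y+, Q4 = x-/y-. Events exactly at a
#' threshold fall on the non-positive side. `Q1+Q2` is the DNA-uptake
#' readout and `Q2+Q3` the protein readout of transfection efficiency.
#'
#' @param sample Viable-gated [event_table()].
#' @param x_threshold,y_threshold Finite thresholds on the `dna_label` and
#'   `protein` channels.
#' @return A `quadrant_stats` object with `$pct` (named percentages summing
#'   to 100; all `NA` when the table is empty) and `$thresholds`.
#' @export
quadrant_stats <- function(sample, x_threshold, y_threshold) {
  if (!is.finite(x_threshold) || !is.finite(y_threshold)) {
    abort_config("quadrant thresholds must be finite")
  }
  n <- n_events(sample)
  if (n == 0) {
    pct <- c(Q1 = NA_real_, Q2 = NA_real_, Q3 = NA_real_, Q4 = NA_real_)
  } else {
    x <- role_values(sample, "dna_label")
    y <- role_values(sample, "protein")
    xp <- x > x_threshold
    yp <- y > y_threshold
    pct <- 100 * c(Q1 = sum(xp & !yp), Q2 = sum(xp & yp),
                   Q3 = sum(!xp & yp), Q4 = sum(!xp & !yp)) / n
  }
  structure(list(pct = pct,
                 thresholds = c(x = x_threshold, y = y_threshold),
                 n = n),
            class = "quadrant_stats")
}

#' @export
print.quadrant_stats <- function(x, ...) {
  cat("<quadrant stats>\n")
  cat(sprintf("  thresholds: x = %.4g, y = %.4g; n = %d\n",
              x$thresholds[["x"]], x$thresholds[["y"]], x$n))
  print(round(x$pct, 2))
  invisible(x)
}

#' Blank-corrected median fluorescence (dMFI)
#'
#' Median fluorescence of the viable-gated sample minus the median of the
#' matched negative control, on untransformed acquisition-scale values. The
#' labeled-DNA channel is corrected against the unlabeled-plasmid control;
#' the protein channel against the zero-timepoint control. Negative values
#' are reported as-is (with a warning), never clipped: clipping would bias
#' reproducibility statistics computed over replicate dMFIs.
#'
#' @param sample,control Viable-gated [event_table()]s.
#' @param role Channel role.
#' @param stat `"median"` (the default and the assay's definition of MFI) or
#'   `"mean"`.
#' @return The blank-corrected MFI in acquisition units.
#' @export
blank_corrected_mfi <- function(sample, control, role, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (n_events(sample) == 0 || n_events(control) == 0) {
    abort_insufficient("blank_corrected_mfi needs non-empty sample and control")
  }
  f <- if (stat == "median") stats::median else mean
  out <- f(role_values(sample, role)) - f(role_values(control, role))
  if (out < 0) {
    warn_cytofect(sprintf("negative blank-corrected MFI (%.4g) on role '%s'",
                          out, role))
  }
  out
}

#' Transfection readouts for one sample
#'
#' The full per-sample computation: gate the sample (singlet, intact against
#' the untransfected control, viability by dye or scatter), gate each
#' control with gates fitted on itself, derive positivity thresholds from
#' the unlabeled-plasmid (DNA channel) and zero-timepoint (protein channel)
#' controls, and compute quadrant percentages, blank-corrected MFIs, and -
#' when a bead calibration is supplied - MESF values and plasmid copies per
#' cell.
#'
#' @param sample An [event_table()] with `dna_label` and `protein` roles.
#' @param controls A [control_set()].
#' @param gating_params Gate parameter overrides (see [gate_sample()]).
#' @param positivity_pct Control percentile for positivity thresholds
#'   (default 99.9).
#' @param calibration Optional [fit_mesf_curve()] result for the DNA-label
#'   channel fluorochrome.
#' @param protein_calibration Optional calibration for the protein channel;
#'   when absent (e.g. mCherry, for which no MESF kit exists), the protein
#'   readout stays in dMFI units.
#' @param plasmid Optional [plasmid_spec()]; with a DNA calibration this
#'   yields plasmid copies and moles per cell.
#' @param mfi_stat Passed to [blank_corrected_mfi()].
#' @return A `transfection_readout` object; use [tidy()] for a one-row
#'   tibble.
#' @export
transfection_readouts <- function(sample, controls, gating_params = list(),
                                  positivity_pct = 99.9,
                                  calibration = NULL,
                                  protein_calibration = NULL,
                                  plasmid = NULL,
                                  mfi_stat = "median") {
  if (!inherits(controls, "control_set")) {
    abort_config("`controls` must be a control_set (untransfected, unlabeled_plasmid, zero_timepoint)")
  }
  for (role in c("dna_label", "protein")) {
    if (!has_role(sample, role)) {
      abort_config(paste0("sample must map role '", role, "'"))
    }
  }

  ref <- controls$untransfected
  g_sample <- gate_sample(sample, reference = ref, params = gating_params)
  sample_v <- viable_events(sample, g_sample)

  # controls are gated with gates fitted on themselves: transfection
  # perturbs scatter, so sample-fitted gates would misplace control boxes
  gate_ctrl <- function(tb) {
    g <- gate_sample(tb, reference = NULL, params = gating_params)
    viable_events(tb, g)
  }
  unl_v <- gate_ctrl(controls$unlabeled_plasmid)
  zer_v <- gate_ctrl(controls$zero_timepoint)

  x_thr <- positivity_threshold(unl_v, "dna_label", pct = positivity_pct)
  y_thr <- positivity_threshold(zer_v, "protein", pct = positivity_pct)
  quad <- quadrant_stats(sample_v, x_thr, y_thr)

  dmfi_dna <- blank_corrected_mfi(sample_v, unl_v, "dna_label", stat = mfi_stat)
  dmfi_protein <- blank_corrected_mfi(sample_v, zer_v, "protein", stat = mfi_stat)

  mesf_dna <- mesf_na <- NA_real_
  extrapolated_dna <- FALSE
  copies <- moles <- NA_real_
  if (!is.null(calibration) && is.finite(dmfi_dna) && dmfi_dna > 0) {
    conv <- mfi_to_mesf(calibration, dmfi_dna)
    mesf_dna <- conv$mesf
    extrapolated_dna <- conv$extrapolated
    if (!is.null(plasmid)) {
      pc <- plasmids_per_cell(mesf_dna, plasmid)
      copies <- pc$copies
      moles <- pc$moles
    }
  }
  mesf_protein <- NA_real_
  if (!is.null(protein_calibration) && is.finite(dmfi_protein) &&
      dmfi_protein > 0) {
    mesf_protein <- mfi_to_mesf(protein_calibration, dmfi_protein)$mesf
  }

  structure(list(
    sample_id = sample_id(sample),
    timepoint_h = timepoint_h(sample),
    pct_dna_pos = unname(quad$pct[["Q1"]] + quad$pct[["Q2"]]),
    pct_protein_pos = unname(quad$pct[["Q2"]] + quad$pct[["Q3"]]),
    dmfi_dna = dmfi_dna,
    dmfi_protein = dmfi_protein,
    mesf_dna = mesf_dna,
    mesf_protein = mesf_protein,
    plasmid_copies_per_cell = copies,
    plasmid_moles_per_cell = moles,
    mesf_dna_extrapolated = extrapolated_dna,
    n_viable = n_events(sample_v),
    quadrants = quad,
    thresholds = c(x_dna_label = x_thr, y_protein = y_thr),
    gating = g_sample,
    viability_method = g_sample$viability_method
  ), class = "transfection_readout")
}

#' @export
print.transfection_readout <- function(x, ...) {
  cat(sprintf("<transfection readout: %s%s>\n", x$sample_id,
              if (is.null(x$timepoint_h)) "" else
                sprintf(" @ %g h", x$timepoint_h)))
  cat(sprintf("  DNA+ %.2f%%  protein+ %.2f%%  (n viable = %d, viability by %s)\n",
              x$pct_dna_pos, x$pct_protein_pos, x$n_viable,
              x$viability_method))
  cat(sprintf("  dMFI: DNA %.4g, protein %.4g\n", x$dmfi_dna, x$dmfi_protein))
  if (is.finite(x$mesf_dna)) {
    cat(sprintf("  MESF(DNA) %.4g%s", x$mesf_dna,
                if (x$mesf_dna_extrapolated) " [extrapolated]" else ""))
    if (is.finite(x$plasmid_copies_per_cell)) {
      cat(sprintf("  -> %.4g plasmid copies/cell", x$plasmid_copies_per_cell))
    }
    cat("\n")
  }
  invisible(x)
}

#' Toxicity readout for one sample
#'
#' Cell death among intact singlets, compared to the untransfected control
#' (gated with gates fitted on itself). Death is called by the viability dye
#' when one is mapped, otherwise by the scatter dead region. When both a dye
#' and a labeled-DNA channel are present, the direct toxicity of the
#' transfection is additionally summarized as the percentage of DNA-positive
#' events that are dye-positive.
#'
#' @param sample,untransfected [event_table()]s.
#' @param gating_params Gate parameter overrides (see [gate_sample()]).
#' @param positivity_pct Percentile for the DNA positivity threshold used in
#'   the dead-among-DNA-positive summary.
#' @return A `toxicity_readout` with fields `pct_dead`, `pct_dead_control`,
#'   `excess_death`, `pct_dead_among_dna_pos`, `method`.
#' @export
toxicity_readout <- function(sample, untransfected, gating_params = list(),
                             positivity_pct = 99.9) {
  p <- utils::modifyList(default_gate_params(), gating_params)

  dead_stats <- function(tb, reference) {
    sg <- fit_singlet_gate(tb, band_width = p$band_width)
    ig <- fit_intact_gate(tb, lower_pct = p$intact_lower_pct,
                          upper_pct = p$intact_upper_pct,
                          reference = reference)
    use_dye <- has_role(tb, "viability") && p$viability %in% c("auto", "dye")
    vg <- if (use_dye) {
      ctrl <- if (!is.null(reference) && has_role(reference, "viability")) {
        reference
      } else tb
      viability_gate_dye(tb, ctrl, pct = p$dye_pct)
    } else {
      viability_gate_scatter(tb, if (is.null(reference)) tb else reference,
                             low_pct = p$scatter_low_pct,
                             high_pct = p$scatter_high_pct)
    }
    res <- apply_hierarchy(tb, sg, ig, vg)
    intact <- res$masks$intact
    dead <- intact & !res$masks$viable
    list(pct_dead = if (sum(intact) == 0) NA_real_ else
           100 * sum(dead) / sum(intact),
         intact = intact, dead = dead,
         method = if (use_dye) "dye" else "scatter")
  }

  s <- dead_stats(sample, untransfected)
  ctl <- dead_stats(untransfected, NULL)

  pct_dead_among_dna_pos <- NA_real_
  if (has_role(sample, "viability") && has_role(sample, "dna_label") &&
      has_role(untransfected, "dna_label")) {
    thr <- positivity_threshold(
      filter_events(untransfected, ctl$intact & !ctl$dead),
      "dna_label", pct = positivity_pct)
    dna_pos <- s$intact & (role_values(sample, "dna_label") > thr)
    if (sum(dna_pos) > 0) {
      pct_dead_among_dna_pos <- 100 * sum(dna_pos & s$dead) / sum(dna_pos)
    }
  }

  structure(list(
    sample_id = sample_id(sample),
    pct_dead = s$pct_dead,
    pct_dead_control = ctl$pct_dead,
    excess_death = s$pct_dead - ctl$pct_dead,
    pct_dead_among_dna_pos = pct_dead_among_dna_pos,
    method = s$method
  ), class = "toxicity_readout")
}

#' @export
print.toxicity_readout <- function(x, ...) {
  cat(sprintf("<toxicity readout: %s (by %s)>\n", x$sample_id, x$method))
  cat(sprintf("  dead %.2f%% (control %.2f%%, excess %.2f)\n",
              x$pct_dead, x$pct_dead_control, x$excess_death))
  if (is.finite(x$pct_dead_among_dna_pos)) {
    cat(sprintf("  dead among DNA+ events: %.2f%%\n", x$pct_dead_among_dna_pos))
  }
  invisible(x)
}
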