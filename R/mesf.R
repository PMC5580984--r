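#' MESF bead calibration and plasmid copy-number conversion
#'
#' MESF (Molecules of Equivalent Soluble Fluorochrome) beads carry known
#' numbers of fluorochrome molecules; running them on the cytometer gives
#' one intensity peak per bead population, and a log-log regression of known
#' MESF on peak MFI turns detector units into absolute fluorochrome counts.
#' Because the labeled plasmid carries a known labeling density (about one
#' fluorochrome per 40 bp), the MESF of the blank-corrected DNA signal
#' converts directly into plasmid copies - and moles - per cell.
#'
#' @name mesf
NULL

AVOGADRO <- 6.02214076e23

#' Bead set
#'
#' @param events Bead intensities: a numeric vector, or an [event_table()]
#'   whose fluorescence channel is given by `channel` (defaults to the
#'   single/first channel).
#' @param known_mesf Ascending vector of the kit's known molecule counts
#'   (length K >= 3).
#' @param has_blank Does the kit include an unlabeled (blank) bead
#'   population? If so, the dimmest detected cluster is discarded.
#' @param channel Channel name when `events` is an event table.
#' @return A `bead_set`.
#' @export
bead_set <- function(events, known_mesf, has_blank = FALSE, channel = NULL) {
  if (inherits(events, "event_tbl") || is.data.frame(events)) {
    if (is.null(channel)) channel <- names(events)[[1]]
    events <- events[[channel]]
  }
  events <- as.numeric(events)
  known_mesf <- as.numeric(known_mesf)
  if (length(known_mesf) < 3) {
    abort_config("a bead kit needs at least 3 known MESF values")
  }
  if (any(known_mesf <= 0) || any(diff(known_mesf) <= 0)) {
    abort_config("known MESF values must be positive and strictly increasing")
  }
  structure(list(events = events, known_mesf = known_mesf,
                 has_blank = isTRUE(has_blank)),
            class = "bead_set")
}

#' Detect bead peak MFIs
#'
#' Partitions bead intensities into K (plus one when a blank population is
#' present) clusters on the log10 scale and reports each cluster's median on
#' the linear scale, sorted ascending and matched to the kit's known MESF
#' values by rank. Clustering is a deterministic Lloyd iteration started
#' from evenly spaced quantile centers. Two adjacent cluster medians within
#' 10% of each other indicate merged peaks and raise a calibration-quality
#' error rather than returning an unreliable curve.
#'
#' @param beads A [bead_set()].
#' @return Numeric vector of K peak MFIs, ascending.
#' @export
detect_bead_peaks <- function(beads) {
  stopifnot(inherits(beads, "bead_set"))
  k_known <- length(beads$known_mesf)
  k <- k_known + as.integer(beads$has_blank)
  x <- beads$events
  if (length(x) < 100 * k_known) {
    abort_insufficient(sprintf(
      "need at least %d bead events for %d populations; got %d",
      100 * k_known, k_known, length(x)))
  }
  lx <- log10(pmax(x, 0) + 1)
  centers <- pctile(lx, 100 * (seq_len(k) - 0.5) / k)
  cl <- lloyd_1d(lx, centers)
  meds <- vapply(seq_len(k), function(i) stats::median(x[cl == i]),
                 numeric(1))
  meds <- sort(meds)
  if (beads$has_blank) meds <- meds[-1]
  rel <- meds[-1] / meds[-length(meds)]
  if (any(rel < 1.10)) {
    rlang::abort(
      "bead populations are not resolved (two cluster medians within 10%); calibration rejected",
      class = "cytofect_calibration_error")
  }
  meds
}

# deterministic 1-D k-means (Lloyd) from fixed initial centers
lloyd_1d <- function(x, centers, max_iter = 200) {
  centers <- sort(centers)
  assign_x <- function(cen) {
    d <- abs(outer(x, cen, "-"))
    max.col(-d, ties.method = "first")
  }
  cl <- assign_x(centers)
  for (i in seq_len(max_iter)) {
    new_cen <- vapply(seq_along(centers), function(j) {
      if (any(cl == j)) mean(x[cl == j]) else centers[j]
    }, numeric(1))
    new_cl <- assign_x(new_cen)
    if (identical(new_cl, cl) && max(abs(new_cen - centers)) < 1e-12) break
    centers <- new_cen
    cl <- new_cl
  }
  cl
}

#' Fit the MESF standard curve
#'
#' Ordinary least squares in log10-log10 space:
#' `log10(MESF) = intercept + slope * log10(MFI)`, each bead peak weighted
#' equally. The fit is rejected (calibration-quality error) when r2 < 0.98,
#' and the peak/known pairing must be monotone.
#'
#' @param peak_mfi Ascending detected peak MFIs.
#' @param known_mesf Ascending known molecule counts, same length.
#' @return A `bead_calibration` with `slope`, `intercept`, `r2`,
#'   `valid_range` and the input peaks.
#' @export
fit_mesf_curve <- function(peak_mfi, known_mesf) {
  if (length(peak_mfi) != length(known_mesf)) {
    abort_data("peak_mfi and known_mesf must have equal length")
  }
  if (any(peak_mfi <= 0) || any(known_mesf <= 0)) {
    abort_data("peak MFIs and known MESF values must be positive")
  }
  if (any(diff(peak_mfi) <= 0) || any(diff(known_mesf) <= 0)) {
    abort_data("non-monotone peak/known MESF pairing")
  }
  lx <- log10(peak_mfi)
  ly <- log10(known_mesf)
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- if (stats::var(ly) == 0) 1 else
    1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  if (r2 < 0.98) {
    rlang::abort(sprintf(
      "MESF standard curve is not log-linear (r2 = %.4f < 0.98); calibration rejected",
      r2), class = "cytofect_calibration_error")
  }
  structure(list(peak_mfi = peak_mfi, known_mesf = known_mesf,
                 slope = slope, intercept = intercept, r2 = r2,
                 valid_range = range(peak_mfi)),
            class = "bead_calibration")
}

#' @export
print.bead_calibration <- function(x, ...) {
  cat("<MESF bead calibration>\n")
  cat(sprintf("  log10(MESF) = %.4f + %.4f * log10(MFI), r2 = %.4f\n",
              x$intercept, x$slope, x$r2))
  cat(sprintf("  valid MFI range: [%.4g, %.4g] (%d peaks)\n",
              x$valid_range[1], x$valid_range[2], length(x$peak_mfi)))
  invisible(x)
}

#' Detect peaks and fit the standard curve in one step
#'
#' @param beads A [bead_set()].
#' @return A `bead_calibration`.
#' @export
calibrate_beads <- function(beads) {
  fit_mesf_curve(detect_bead_peaks(beads), beads$known_mesf)
}

#' Convert MFI to MESF
#'
#' @param cal A `bead_calibration`.
#' @param mfi Positive MFI value(s) on the acquisition scale (typically a
#'   blank-corrected MFI, which must be positive to be standardized).
#' @return List with `mesf` and logical `extrapolated` (MFI outside the
#'   calibrated bead range; the value is still returned but flagged).
#' @export
mfi_to_mesf <- function(cal, mfi) {
  stopifnot(inherits(cal, "bead_calibration"))
  if (any(!is.finite(mfi)) || any(mfi <= 0)) {
    abort_domain("MFI must be positive to convert to MESF")
  }
  mesf <- 10^(cal$intercept + cal$slope * log10(mfi))
  list(mesf = mesf,
       extrapolated = mfi < cal$valid_range[1] | mfi > cal$valid_range[2])
}

#' Plasmid description
#'
#' @param name Plasmid name.
#' @param length_bp Plasmid length in base pairs.
#' @param bp_per_label Average base pairs per attached fluorochrome label
#'   (default 40, the nominal labeling density of covalent one-step DNA
#'   labeling kits).
#' @return A `plasmid_spec`.
#' @export
plasmid_spec <- function(name, length_bp, bp_per_label = 40) {
  length_bp <- as.numeric(length_bp)
  if (length_bp <= 0 || length_bp != round(length_bp)) {
    abort_config("length_bp must be a positive integer")
  }
  if (bp_per_label <= 0) abort_config("bp_per_label must be positive")
  if (length_bp < bp_per_label) {
    abort_config("plasmid must be at least bp_per_label long")
  }
  structure(list(name = name, length_bp = length_bp,
                 bp_per_label = bp_per_label),
            class = "plasmid_spec")
}

#' Fluorochrome labels per plasmid molecule
#'
#' `length_bp / bp_per_label`, real-valued (no rounding): e.g. a 14825 bp
#' plasmid at one label per 40 bp carries 370.625 labels on average.
#'
#' @param spec A [plasmid_spec()].
#' @return Average labels per plasmid.
#' @export
labels_per_plasmid <- function(spec) {
  stopifnot(inherits(spec, "plasmid_spec"))
  spec$length_bp / spec$bp_per_label
}

#' Plasmid copies and moles per cell from MESF
#'
#' Divides the per-cell MESF of the DNA-label fluorochrome by the average
#' number of labels per plasmid; moles follow by Avogadro's number.
#'
#' @param mesf_fitc Non-negative MESF of the DNA-label channel per cell.
#' @param spec A [plasmid_spec()].
#' @return List with `copies` and `moles` per cell.
#' @export
plasmids_per_cell <- function(mesf_fitc, spec) {
  if (any(mesf_fitc < 0)) abort_domain("MESF must be non-negative")
  copies <- mesf_fitc / labels_per_plasmid(spec)
  list(copies = copies, moles = copies / AVOGADRO)
}
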