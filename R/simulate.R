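#' Synthetic cytometry simulator
#'
#' A seeded generator of event tables with per-event ground truth, emulating
#' the population structure of a transfection experiment: viable
#' untransfected cells, viable transfected cells with correlated DNA-label
#' and protein fluorescence, an optional protein-positive/DNA-negative
#' subpopulation, dead cells (scatter-shifted and dye-bright), debris, and
#' doublets. Fluorescence is lognormal per population; the DNA/protein rank
#' correlation of transfected cells is imposed through a Gaussian copula, so
#' the target Spearman correlation is achieved independently of the marginal
#' scales. Doublets sum the area channels of two sampled singlets and take
#' the larger pulse height, which breaks the FSC-H/FSC-A ratio exactly the
#' way real doublets do.
#'
#' Default parameter values are stored in a versioned JSON shipped with the
#' package (`system.file("extdata", "sim_default.json", package =
#' "cytofect")`), so simulation-based checks are reproducible.
#'
#' @name simulate
NULL

#' Default simulation configuration
#'
#' Builds a full simulation configuration from high-level knobs, with all
#' distributional parameters taken from the packaged defaults file. The
#' defaults describe a chemically transfected adherent cell line harvested
#' 24 h post transfection: 60% of viable cells transfected (typical for a
#' permissive line under chemical transfection, and above one half, so the
#' viable-cell median fluorescence sits inside the transfected population
#' and blank-corrected MFIs track signal kinetics), 12% dead cells, 8%
#' debris, 5% doublets, uptake kinetics peaking at 12 h and protein
#' expression saturating towards 48 h.
#'
#' @param n_events Number of events per sample.
#' @param seed Integer seed; every stochastic step derives from it.
#' @param transfected_fraction Fraction of *viable* cells that carry the
#'   labeled plasmid.
#' @param protein_only_fraction Fraction of viable cells that express
#'   protein without detectable DNA-label fluorescence (the
#'   protein+/DNA- phenotype seen late after transfection).
#' @param dead_fraction,debris_fraction,doublet_fraction Mixture fractions.
#' @param timepoint_h Harvest time in hours; scales the DNA and protein
#'   brightness through the kinetic model.
#' @param dna_protein_rank_corr Target Spearman correlation between DNA and
#'   protein signal in transfected cells.
#' @param dna_shift,protein_shift Peak fold-change of the transfected
#'   population's DNA-label / protein median over autofluorescence
#'   (overrides the packaged defaults when given).
#' @param include_viability_dye Map a viability-dye channel? Set `FALSE` to
#'   emulate electroporation samples where dyes cannot be used.
#' @return A `sim_config` list.
#' @export
default_sim_config <- function(n_events = 20000, seed = 1,
                               transfected_fraction = 0.60,
                               protein_only_fraction = 0,
                               dead_fraction = 0.12,
                               debris_fraction = 0.08,
                               doublet_fraction = 0.05,
                               timepoint_h = 24,
                               dna_protein_rank_corr = 0.7,
                               dna_shift = NULL, protein_shift = NULL,
                               include_viability_dye = TRUE) {
  if (n_events < 1) abort_config("n_events must be >= 1")
  if (doublet_fraction < 0 || doublet_fraction >= 0.5) {
    abort_config("doublet_fraction must be in [0, 0.5)")
  }
  base <- sim_defaults()
  if (is.null(dna_shift)) dna_shift <- base$signal$dna_shift
  if (is.null(protein_shift)) protein_shift <- base$signal$protein_shift

  viable <- 1 - dead_fraction - debris_fraction
  if (viable <= 0) abort_config("dead + debris fractions must leave viable cells")
  f_tr <- transfected_fraction * viable
  f_po <- protein_only_fraction * viable
  f_un <- viable - f_tr - f_po
  if (f_un < -1e-9) {
    abort_config("transfected + protein-only fractions exceed 1")
  }
  f_un <- max(f_un, 0)

  kin <- base$kinetics
  dna_scale <- uptake_pulse(timepoint_h, kin$uptake_peak_h, kin$uptake_shape)
  prot_scale <- protein_rise(timepoint_h, kin$protein_t50_h, kin$protein_hill)

  structure(list(
    n_events = as.integer(n_events),
    seed = as.integer(seed),
    doublet_fraction = doublet_fraction,
    timepoint_h = timepoint_h,
    include_viability_dye = include_viability_dye,
    kinetics = kin,
    signal = list(dna_shift = dna_shift, protein_shift = protein_shift),
    populations = list(
      sim_population("viable_untransfected", f_un, base),
      sim_population("viable_transfected", f_tr, base,
                     dna_mult = dna_shift * dna_scale,
                     protein_mult = protein_shift * prot_scale,
                     dna_protein_rank_corr = dna_protein_rank_corr),
      sim_population("protein_only", f_po, base,
                     protein_mult = protein_shift * prot_scale),
      sim_population("dead", dead_fraction, base,
                     fsc_mult = base$dead$fsc_mult,
                     ssc_mult = base$dead$ssc_mult,
                     dye_positive = TRUE),
      sim_population("debris", debris_fraction, base,
                     fsc_mult = base$debris$fsc_mult,
                     ssc_mult = base$debris$ssc_mult,
                     fsc_sdlog = base$debris$fsc_sdlog,
                     ssc_sdlog = base$debris$ssc_sdlog)
    )
  ), class = "sim_config")
}

sim_defaults <- function() {
  path <- system.file("extdata", "sim_default.json", package = "cytofect")
  if (path == "") {
    abort_config("packaged simulator defaults not found")
  }
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Define one simulated population
#'
#' @param name Population label carried into the ground truth.
#' @param fraction Mixture fraction.
#' @param base Packaged defaults list (see [default_sim_config()]).
#' @param fsc_mult,ssc_mult Multiplicative scatter shifts relative to the
#'   viable baseline.
#' @param dna_mult,protein_mult Multiplicative fluorescence shifts over
#'   autofluorescence.
#' @param fsc_sdlog,ssc_sdlog Optional overrides for the scatter log-sd.
#' @param dna_protein_rank_corr Target Spearman correlation between the DNA
#'   and protein channel within this population.
#' @param dye_positive Is this population stained by the viability dye?
#' @return A population description list.
#' @export
sim_population <- function(name, fraction, base = sim_defaults(),
                           fsc_mult = 1, ssc_mult = 1,
                           dna_mult = 1, protein_mult = 1,
                           fsc_sdlog = NULL, ssc_sdlog = NULL,
                           dna_protein_rank_corr = 0,
                           dye_positive = FALSE) {
  sc <- base$scatter
  fl <- base$fluor
  list(
    name = name, fraction = fraction,
    fsc_meanlog = log(sc$fsc_median * fsc_mult),
    fsc_sdlog = if (is.null(fsc_sdlog)) sc$fsc_sdlog else fsc_sdlog,
    ssc_meanlog = log(sc$ssc_median * ssc_mult),
    ssc_sdlog = if (is.null(ssc_sdlog)) sc$ssc_sdlog else ssc_sdlog,
    h_ratio = sc$h_ratio, h_noise_sd = sc$h_noise_sd,
    dna_meanlog = log(fl$dna_autofluor * dna_mult),
    dna_sdlog = if (dna_mult > 1) fl$dna_sdlog_bright else fl$dna_sdlog,
    protein_meanlog = log(fl$protein_autofluor * protein_mult),
    protein_sdlog = if (protein_mult > 1) fl$protein_sdlog_bright else fl$protein_sdlog,
    via_meanlog = log(if (dye_positive) fl$dye_dead_median else fl$dye_viable_median),
    via_sdlog = if (dye_positive) fl$dye_dead_sdlog else fl$dye_viable_sdlog,
    dna_protein_rank_corr = dna_protein_rank_corr,
    dye_positive = dye_positive
  )
}

uptake_pulse <- function(t, peak_h, shape) {
  ifelse(t <= 0, 0, (t / peak_h)^shape * exp(shape * (1 - t / peak_h)))
}

protein_rise <- function(t, t50_h, hill) {
  ifelse(t <= 0, 0, t^hill / (t50_h^hill + t^hill))
}

#' Simulate one sample with ground truth
#'
#' @param cfg A `sim_config` (see [default_sim_config()]).
#' @return List with `events` (an [event_table()]) and `truth` (tibble with
#'   one `population` label and one `doublet` flag per event).
#' @export
simulate_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fr <- vapply(cfg$populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    abort_config(sprintf("population fractions sum to %.6f, not 1", sum(fr)))
  }
  withr::local_seed(cfg$seed)
  draw_sample_events(cfg)
}

# draws under the *current* RNG state (callers manage seeding)
draw_sample_events <- function(cfg, timepoint_h = cfg$timepoint_h,
                               sample_id = "sim_sample") {
  n <- cfg$n_events
  n_doub <- as.integer(round(cfg$doublet_fraction * n))
  n_single <- n - n_doub

  fr <- vapply(cfg$populations, `[[`, numeric(1), "fraction")
  pop_names <- vapply(cfg$populations, `[[`, character(1), "name")
  keep <- fr > 0
  draw_one_set <- function(m) {
    pool <- which(keep)
    idx <- pool[sample.int(length(pool), m, replace = TRUE, prob = fr[keep])]
    out <- matrix(0, nrow = m, ncol = 6)
    colnames(out) <- c("fsc_a", "fsc_h", "ssc_a", "dna", "protein", "via")
    for (j in unique(idx)) {
      p <- cfg$populations[[j]]
      rows <- which(idx == j)
      k <- length(rows)
      fsc <- stats::rlnorm(k, p$fsc_meanlog, p$fsc_sdlog)
      ssc <- stats::rlnorm(k, p$ssc_meanlog, p$ssc_sdlog)
      fsc_h <- p$h_ratio * fsc * (1 + stats::rnorm(k, 0, p$h_noise_sd))
      rs <- p$dna_protein_rank_corr
      if (abs(rs) > 0) {
        # Gaussian copula calibrated so the *Spearman* correlation hits rs
        rho <- 2 * sin(pi * rs / 6)
        z1 <- stats::rnorm(k)
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(k)
        dna <- exp(p$dna_meanlog + p$dna_sdlog * z1)
        prot <- exp(p$protein_meanlog + p$protein_sdlog * z2)
      } else {
        dna <- stats::rlnorm(k, p$dna_meanlog, p$dna_sdlog)
        prot <- stats::rlnorm(k, p$protein_meanlog, p$protein_sdlog)
      }
      via <- stats::rlnorm(k, p$via_meanlog, p$via_sdlog)
      out[rows, ] <- cbind(fsc, fsc_h, ssc, dna, prot, via)
    }
    list(values = out, pop = pop_names[idx])
  }

  singles <- draw_one_set(n_single)
  values <- singles$values
  pops <- singles$pop
  doublet <- rep(FALSE, n_single)

  if (n_doub > 0) {
    a <- draw_one_set(n_doub)
    b <- draw_one_set(n_doub)
    dv <- a$values
    # area channels add; pulse height takes the larger of the pair
    for (col in c("fsc_a", "ssc_a", "dna", "protein", "via")) {
      dv[, col] <- a$values[, col] + b$values[, col]
    }
    dv[, "fsc_h"] <- pmax(a$values[, "fsc_h"], b$values[, "fsc_h"])
    values <- rbind(values, dv)
    pops <- c(pops, a$pop)
    doublet <- c(doublet, rep(TRUE, n_doub))
  }

  ord <- sample.int(nrow(values))
  values <- values[ord, , drop = FALSE]
  pops <- pops[ord]
  doublet <- doublet[ord]

  df <- tibble::tibble(
    `FSC-A` = values[, "fsc_a"], `FSC-H` = values[, "fsc_h"],
    `SSC-A` = values[, "ssc_a"], `FITC-A` = values[, "dna"],
    `mCherry-A` = values[, "protein"]
  )
  roles <- c("FSC-A" = "fsc_a", "FSC-H" = "fsc_h", "SSC-A" = "ssc_a",
             "FITC-A" = "dna_label", "mCherry-A" = "protein")
  if (cfg$include_viability_dye) {
    df$`7AAD-A` <- values[, "via"]
    roles <- c(roles, "7AAD-A" = "viability")
  }
  events <- event_table(df, roles = roles, sample_id = sample_id,
                        timepoint_h = timepoint_h)
  list(events = events,
       truth = tibble::tibble(population = pops, doublet = doublet))
}

#' Simulate the three negative controls
#'
#' * untransfected: a clean reference culture (trace dead cells and debris,
#'   no DNA or protein signal over autofluorescence);
#' * unlabeled_plasmid: the sample's composition with protein expression but
#'   DNA-label at autofluorescence;
#' * zero_timepoint: harvested right after transfection - some DNA-label
#'   signal (uptake begins quickly) but no protein over autofluorescence.
#'
#' @param cfg A `sim_config`.
#' @return A [control_set()]; each table also carries its ground truth in
#'   attribute `"truth"`.
#' @export
simulate_controls <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  base <- sim_defaults()
  withr::local_seed(cfg$seed + 1L)

  make <- function(sub_cfg, id, timepoint_h) {
    out <- draw_sample_events(sub_cfg, timepoint_h = timepoint_h,
                              sample_id = id)
    attr(out$events, "truth") <- out$truth
    out$events
  }

  clean <- cfg
  clean$populations <- list(
    sim_population("viable_untransfected",
                   1 - base$control$dead_fraction - base$control$debris_fraction,
                   base),
    sim_population("dead", base$control$dead_fraction, base,
                   fsc_mult = base$dead$fsc_mult,
                   ssc_mult = base$dead$ssc_mult, dye_positive = TRUE),
    sim_population("debris", base$control$debris_fraction, base,
                   fsc_mult = base$debris$fsc_mult,
                   ssc_mult = base$debris$ssc_mult,
                   fsc_sdlog = base$debris$fsc_sdlog,
                   ssc_sdlog = base$debris$ssc_sdlog)
  )
  untransfected <- make(clean, "untransfected", cfg$timepoint_h)

  strip_role <- function(sub_cfg, what = c("dna", "protein")) {
    what <- match.arg(what)
    sub_cfg$populations <- lapply(sub_cfg$populations, function(p) {
      if (what == "dna") {
        p$dna_meanlog <- log(base$fluor$dna_autofluor)
        p$dna_sdlog <- base$fluor$dna_sdlog
      } else {
        p$protein_meanlog <- log(base$fluor$protein_autofluor)
        p$protein_sdlog <- base$fluor$protein_sdlog
      }
      p$dna_protein_rank_corr <- 0
      p
    })
    sub_cfg
  }

  unlabeled <- strip_role(cfg, "dna")
  unlabeled_plasmid <- make(unlabeled, "unlabeled_plasmid", cfg$timepoint_h)

  zero <- strip_role(cfg, "protein")
  t0 <- sim_defaults()$control$zero_timepoint_h
  scale0 <- uptake_pulse(t0, cfg$kinetics$uptake_peak_h,
                         cfg$kinetics$uptake_shape) /
    max(uptake_pulse(cfg$timepoint_h, cfg$kinetics$uptake_peak_h,
                     cfg$kinetics$uptake_shape), 1e-12)
  zero$populations <- lapply(zero$populations, function(p) {
    if (p$name %in% c("viable_transfected")) {
      p$dna_meanlog <- p$dna_meanlog + log(max(scale0, 1e-12))
      p$dna_meanlog <- max(p$dna_meanlog, log(base$fluor$dna_autofluor))
    }
    p
  })
  zero_timepoint <- make(zero, "zero_timepoint", 0)

  control_set(untransfected, unlabeled_plasmid, zero_timepoint)
}

#' Simulate a transfection time course
#'
#' The transfected population's DNA-label median follows a gamma-shaped
#' pulse peaking at the configured uptake peak time; the protein median
#' follows a Hill-type rise saturating towards the configured saturation
#' time. Each timepoint uses a seed-derived substream, so the whole course
#' is reproducible from the root seed.
#'
#' @param cfg A `sim_config`.
#' @param timepoints Increasing vector of hours post transfection.
#' @return A list, one element per timepoint, each with `timepoint_h`,
#'   `events`, `truth`.
#' @export
simulate_timecourse <- function(cfg, timepoints) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(timepoints) == 0) return(list())
  if (any(diff(timepoints) <= 0)) {
    abort_config("timepoints must be strictly increasing")
  }
  kin <- cfg$kinetics
  purrr::map2(timepoints, seq_along(timepoints), function(t, i) {
    sub <- cfg
    dna_scale <- uptake_pulse(t, kin$uptake_peak_h, kin$uptake_shape)
    prot_scale <- protein_rise(t, kin$protein_t50_h, kin$protein_hill)
    base <- sim_defaults()
    sub$populations <- lapply(sub$populations, function(p) {
      if (p$name == "viable_transfected") {
        p$dna_meanlog <- log(max(base$fluor$dna_autofluor *
                                   cfg$signal$dna_shift * dna_scale,
                                 base$fluor$dna_autofluor))
        p$protein_meanlog <- log(max(base$fluor$protein_autofluor *
                                       cfg$signal$protein_shift * prot_scale,
                                     base$fluor$protein_autofluor))
      }
      if (p$name == "protein_only") {
        p$protein_meanlog <- log(max(base$fluor$protein_autofluor *
                                       cfg$signal$protein_shift * prot_scale,
                                     base$fluor$protein_autofluor))
      }
      p
    })
    withr::local_seed((cfg$seed + 7919L * i) %% .Machine$integer.max)
    out <- draw_sample_events(sub, timepoint_h = t,
                              sample_id = sprintf("t%02gh", t))
    list(timepoint_h = t, events = out$events, truth = out$truth)
  })
}

#' Simulate an MESF bead acquisition
#'
#' Bead events are lognormal around each configured peak MFI with the given
#' coefficient of variation (the median of each population equals its peak
#' MFI); the kit's known MESF values derive from the true power law
#' `log10(MESF) = true_intercept + true_slope * log10(MFI)`.
#'
#' @param true_slope,true_intercept True standard-curve parameters.
#' @param peak_mfis Increasing peak MFIs (default: the packaged 5-peak kit).
#' @param cv_per_peak Per-peak coefficient of variation (default 0.08).
#' @param n_per_peak Events per bead population.
#' @param seed Integer seed.
#' @param has_blank Prepend an unlabeled (blank) bead population?
#' @return A [bead_set()] whose `known_mesf` holds the true values.
#' @export
simulate_beads <- function(true_slope = 1, true_intercept = 2,
                           peak_mfis = NULL, cv_per_peak = 0.08,
                           n_per_peak = 500, seed = 1, has_blank = FALSE) {
  base <- sim_defaults()
  if (is.null(peak_mfis)) peak_mfis <- base$beads$peak_mfis
  if (any(diff(peak_mfis) <= 0)) {
    abort_config("peak_mfis must be strictly increasing")
  }
  withr::local_seed(seed)
  known <- 10^(true_intercept + true_slope * log10(peak_mfis))
  sdlog <- sqrt(log(1 + cv_per_peak^2))
  draw <- function(m) stats::rlnorm(n_per_peak, log(m), sdlog)
  ev <- unlist(lapply(peak_mfis, draw))
  if (has_blank) {
    ev <- c(stats::rlnorm(n_per_peak, log(base$beads$blank_mfi), sdlog + 0.1),
            ev)
  }
  bead_set(sample(ev), known_mesf = known, has_blank = has_blank)
}
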