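#' Study-level statistics
#'
#' Analyses that operate across samples, assays and timepoints: time-course
#' peak finding for uptake and expression kinetics, normalization to an
#' experimental control, inter-assay coefficients of variation (the
#' reproducibility currency of the assay), Spearman correlations between
#' readouts, and nonparametric group comparisons.
#'
#' @name study_stats
NULL

#' Find peak timepoints in a transfection time course
#'
#' The argmax over the *measured* timepoints of the blank-corrected DNA and
#' protein signals - no interpolation, because kinetics are reported at
#' sampled times. Ties resolve to the earliest timepoint.
#'
#' @param tc Data frame with columns `timepoint_h`, `dmfi_dna`,
#'   `dmfi_protein` (one row per timepoint; e.g. `tidy()` output of
#'   per-timepoint readouts). Timepoints must be strictly increasing after
#'   sorting.
#' @return Tibble with one row: `t_peak_dna`, `t_peak_protein` (hours).
#' @export
timecourse_peaks <- function(tc) {
  tc <- tibble::as_tibble(tc)
  need <- c("timepoint_h", "dmfi_dna", "dmfi_protein")
  if (!all(need %in% names(tc))) {
    abort_usage(paste0("time course needs columns: ", toString(need)))
  }
  if (nrow(tc) < 2) {
    abort_insufficient("need at least 2 timepoints for peak finding")
  }
  tc <- dplyr::arrange(tc, .data$timepoint_h)
  if (any(diff(tc$timepoint_h) <= 0)) {
    abort_data("timepoints must be strictly increasing")
  }
  tibble::tibble(
    t_peak_dna = tc$timepoint_h[[which.max(tc$dmfi_dna)]],
    t_peak_protein = tc$timepoint_h[[which.max(tc$dmfi_protein)]]
  )
}

#' Normalize readouts to the experimental control mean
#'
#' Expresses each value as a percentage of the mean of the experiment's
#' control values, so that replicate experiments with different absolute
#' scales can be pooled.
#'
#' @param values Numeric readouts.
#' @param control_values Numeric control readouts from the same experiment.
#' @return `values * 100 / mean(control_values)`.
#' @export
normalize_to_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m == 0) {
    abort_domain("control mean is zero or non-finite; cannot normalize")
  }
  values * 100 / m
}

#' Inter-assay coefficient of variation
#'
#' For each sample, the CV across independent assays:
#' `100 * sd / mean` with the sample (n-1) standard deviation. Samples with
#' non-positive mean get an undefined (NA) CV, are flagged with a warning
#' and excluded from the mean CV.
#'
#' @param m Either a numeric matrix (assays in rows, samples in columns) or
#'   a long data frame with columns `assay`, `sample`, `value`.
#' @return List: `per_sample` (tibble of sample, mean, sd, cv), `mean_cv`,
#'   `cv_range`.
#' @export
interassay_cv <- function(m) {
  if (is.matrix(m)) {
    if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
    long <- tidyr::pivot_longer(
      dplyr::mutate(tibble::as_tibble(m, .name_repair = "minimal"),
                    assay = dplyr::row_number()),
      -"assay", names_to = "sample", values_to = "value")
  } else {
    long <- tibble::as_tibble(m)
    if (!all(c("assay", "sample", "value") %in% names(long))) {
      abort_usage("long input needs columns assay, sample, value")
    }
  }
  counts <- dplyr::count(long, .data$sample)
  if (any(counts$n < 2)) {
    abort_insufficient("need at least 2 assays per sample for a CV")
  }
  per_sample <- dplyr::summarise(
    dplyr::group_by(long, .data$sample),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    .groups = "drop")
  per_sample <- dplyr::mutate(
    per_sample,
    cv = dplyr::if_else(.data$mean > 0, 100 * .data$sd / .data$mean,
                        NA_real_))
  if (anyNA(per_sample$cv)) {
    warn_cytofect("sample(s) with non-positive mean: CV undefined, excluded from mean CV")
  }
  ok <- per_sample$cv[!is.na(per_sample$cv)]
  list(per_sample = per_sample,
       mean_cv = mean(ok),
       cv_range = if (length(ok) > 0) range(ok) else c(NA_real_, NA_real_))
}

#' Spearman correlation between two readouts
#'
#' Spearman's rho with average ranks for ties. The two-sided p value is
#' computed by exact permutation of one rank vector for n <= 9 and by the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return Tibble with `rho`, `p_value`, `n`, `method`.
#' @export
correlate_readouts <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort_usage("x and y must have equal length")
  if (n < 4) abort_insufficient("need at least 4 pairs for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_data("constant input: Spearman correlation undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perm <- permutations_of(n)
    rhos <- as.vector(stats::cor(rx, matrix(ry[t(perm)], nrow = n)))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method)
}

# all permutations of 1..n as an (n!) x n matrix
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}

#' Nonparametric group comparisons
#'
#' Kruskal-Wallis for two or more groups, Mann-Whitney (Wilcoxon rank-sum)
#' for exactly two; both with average-rank tie correction and asymptotic p
#' values, delegating to `stats::kruskal.test()` and `stats::wilcox.test()`.
#'
#' @param groups List of numeric vectors (each n >= 3).
#' @param test `"kruskal_wallis"` or `"mann_whitney"`.
#' @return Tibble with `statistic`, `p_value`, `test`.
#' @export
compare_groups <- function(groups, test = c("kruskal_wallis", "mann_whitney")) {
  test <- match.arg(test)
  if (!is.list(groups) || length(groups) < 2) {
    abort_usage("`groups` must be a list of at least 2 numeric vectors")
  }
  if (any(vapply(groups, length, integer(1)) < 3)) {
    abort_usage("each group needs at least 3 observations")
  }
  if (test == "mann_whitney") {
    if (length(groups) != 2) {
      abort_usage("mann_whitney compares exactly 2 groups")
    }
    ht <- suppressWarnings(
      stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE,
                         correct = FALSE))
    stat <- unname(ht$statistic)   # U of the first group
  } else {
    ht <- stats::kruskal.test(groups)
    stat <- unname(ht$statistic)
  }
  tibble::tibble(statistic = stat, p_value = ht$p.value, test = test)
}

#' Compare reproducibility across readouts by ANOVA on CVs
#'
#' One-way ANOVA of per-sample inter-assay CVs grouped by readout, to ask
#' whether one readout is systematically more reproducible than the others.
#' Normality of CVs is not checked; this mirrors common practice for small
#' reproducibility panels and is noted as an assumption.
#'
#' @param cv_df Data frame with columns `readout` and `cv`.
#' @return Tibble with `f_statistic`, `p_value`, `df_between`, `df_within`.
#' @export
compare_readout_cvs <- function(cv_df) {
  cv_df <- tibble::as_tibble(cv_df)
  if (!all(c("readout", "cv") %in% names(cv_df))) {
    abort_usage("cv_df needs columns readout and cv")
  }
  cv_df <- dplyr::filter(cv_df, is.finite(.data$cv))
  if (dplyr::n_distinct(cv_df$readout) < 2) {
    abort_usage("need at least 2 readouts to compare")
  }
  fit <- stats::aov(cv ~ factor(readout), data = cv_df)
  s <- summary(fit)[[1]]
  tibble::tibble(f_statistic = s[["F value"]][1],
                 p_value = s[["Pr(>F)"]][1],
                 df_between = s[["Df"]][1],
                 df_within = s[["Df"]][2])
}
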