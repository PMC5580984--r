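test_that("time-course peaks are the argmax over measured timepoints", {
  tc <- tibble::tibble(timepoint_h = c(6, 12, 24, 48),
                       dmfi_dna = c(50, 90, 60, 20),
                       dmfi_protein = c(5, 20, 60, 90))
  pk <- timecourse_peaks(tc)
  expect_equal(pk$t_peak_dna, 12)
  expect_equal(pk$t_peak_protein, 48)   # monotone series: last timepoint

  # ties resolve to the earliest timepoint
  flat <- tibble::tibble(timepoint_h = c(6, 12, 24),
                         dmfi_dna = 1, dmfi_protein = 1)
  expect_equal(unlist(timecourse_peaks(flat)),
               c(t_peak_dna = 6, t_peak_protein = 6))

  # invariant to adding a timepoint with lower readout
  tc2 <- dplyr::bind_rows(tc, tibble::tibble(timepoint_h = 72,
                                             dmfi_dna = 1, dmfi_protein = 1))
  expect_equal(timecourse_peaks(tc2)$t_peak_dna, 12)

  expect_error(timecourse_peaks(tc[1, ]),
               class = "cytofect_insufficient_data_error")
})

test_that("normalization expresses values as percent of the control mean", {
  expect_equal(mean(normalize_to_control(c(3, 4, 5), c(3, 4, 5))), 100)
  expect_equal(normalize_to_control(c(80, 120), c(90, 100, 110)), c(80, 120))
  # three experiments, different scales, same 0.9 relative effect
  pooled <- unlist(lapply(c(1, 10, 250), function(scale) {
    normalize_to_control(0.9 * scale * c(1, 1, 1), scale * c(1, 1, 1))
  }))
  expect_equal(median(pooled), 90)
  expect_error(normalize_to_control(1:3, c(-1, 1)),
               class = "cytofect_domain_error")
})

test_that("inter-assay CV matches hand arithmetic and is scale invariant", {
  m <- matrix(c(90, 100, 110), ncol = 1)
  cv <- interassay_cv(m)
  expect_equal(cv$per_sample$cv, 10)       # sd 10, mean 100
  expect_equal(cv$mean_cv, 10)

  same <- interassay_cv(matrix(rep(42, 6), ncol = 2))
  expect_equal(same$per_sample$cv, c(0, 0))

  withr::with_seed(51, {
    x <- matrix(rlnorm(30, log(100), 0.2), nrow = 5)
    for (c_scale in c(0.2, 5, 1000)) {
      expect_equal(interassay_cv(c_scale * x)$per_sample$cv,
                   interassay_cv(x)$per_sample$cv)
    }
    # brute-force two-pass sd/mean at 1e-12 relative
    cv2 <- interassay_cv(x)
    brute <- apply(x, 2, function(col) {
      mu <- sum(col) / length(col)
      s <- sqrt(sum((col - mu)^2) / (length(col) - 1))
      100 * s / mu
    })
    expect_equal(cv2$per_sample$cv, unname(brute), tolerance = 1e-12)
  })
})

test_that("CV of samples with non-positive mean is flagged and excluded", {
  m <- matrix(c(90, 100, 110, -5, 0, 5), ncol = 2)
  expect_warning(cv <- interassay_cv(m), class = "cytofect_warning")
  expect_true(is.na(cv$per_sample$cv[2]))
  expect_equal(cv$mean_cv, 10)
})

test_that("Spearman correlation honors monotone invariance and hand ranks", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_readouts(x, x^2)$rho, 1)
  expect_equal(correlate_readouts(x, rev(x))$rho, -1)
  # y = (2,3,1,4,5): d = (-1,-1,2,0,0), sum d^2 = 6,
  # rho = 1 - 6*6/(5*24) = 0.7 by hand rank computation
  y <- c(2, 3, 1, 4, 5)
  r <- correlate_readouts(x, y)
  expect_equal(r$rho, 0.7)
  expect_equal(r$method, "exact permutation")
  # independent oracle: exact p from the classical null distribution
  ct <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(r$p_value, unname(ct$p.value))
  # invariance under strictly monotone transforms of either argument
  expect_equal(correlate_readouts(exp(x), y)$rho, 0.7)
  expect_equal(correlate_readouts(x, log(y))$rho, 0.7)
})

test_that("Spearman edge cases are signaled", {
  expect_error(correlate_readouts(1:3, 1:3),
               class = "cytofect_insufficient_data_error")
  expect_error(correlate_readouts(rep(1, 5), 1:5),
               class = "cytofect_data_error")
  # large-n branch uses the t approximation
  withr::with_seed(52, {
    x <- rnorm(40); y <- x + rnorm(40)
  })
  r <- correlate_readouts(x, y)
  expect_equal(r$method, "t approximation")
  expect_lt(r$p_value, 0.001)
})

test_that("group comparisons match rank-test behavior", {
  same <- compare_groups(list(c(1, 2, 3), c(1, 2, 3)), "mann_whitney")
  expect_equal(same$statistic, 4.5)  # null center of U for n = 3,3
  expect_gt(same$p_value, 0.95)

  sep <- compare_groups(list(c(1, 2, 3), c(101, 102, 103)), "mann_whitney")
  expect_true(sep$statistic %in% c(0, 9))
  expect_lt(sep$p_value, 0.06)       # minimal asymptotic p for n = 3,3

  expect_error(compare_groups(list(1:5), "kruskal_wallis"),
               class = "cytofect_usage_error")
  expect_error(compare_groups(list(1:5, 1:5, 1:5), "mann_whitney"),
               class = "cytofect_usage_error")
  expect_error(compare_groups(list(1:2, 1:5), "mann_whitney"),
               class = "cytofect_usage_error")
})

test_that("Kruskal-Wallis and Mann-Whitney agree on two-group decisions", {
  withr::with_seed(53, {
    agree <- vapply(1:50, function(i) {
      a <- rnorm(20)
      b <- rnorm(20, mean = sample(c(0, 1), 1))
      kw <- compare_groups(list(a, b), "kruskal_wallis")$p_value
      mw <- compare_groups(list(a, b), "mann_whitney")$p_value
      (kw < 0.05) == (mw < 0.05)
    }, logical(1))
  })
  expect_gte(mean(agree), 0.95)
})

test_that("ANOVA on CVs detects a clearly more reproducible readout", {
  withr::with_seed(54, {
    cv_df <- tibble::tibble(
      readout = rep(c("mesf_dna", "pct_dna_pos", "pct_protein_pos"), each = 6),
      cv = c(rnorm(6, 8, 1), rnorm(6, 13, 1), rnorm(6, 12, 1))
    )
  })
  res <- compare_readout_cvs(cv_df)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$df_between, 2)
  expect_error(compare_readout_cvs(tibble::tibble(readout = "a", cv = 1)),
               class = "cytofect_usage_error")
})
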