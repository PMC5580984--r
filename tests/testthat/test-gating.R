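test_that("singlet gate excludes a doublet-like event from a tight population", {
  # 99 events at H/A ratio 0.9, one at 0.45 (area doubled): 0.45 < 0.9 * 0.85
  fsc_a <- c(rep(100, 99), 200)
  fsc_h <- c(rep(90, 99), 90)
  tb <- make_table(fsc_a, fsc_h = fsc_h)
  g <- fit_singlet_gate(tb, band_width = 0.15)
  pass <- gate_pass(g, tb)
  expect_true(all(pass[1:99]))
  expect_false(pass[100])
})

test_that("singlet gate passes identical events and enforces preconditions", {
  tb <- make_table(rep(100, 60), fsc_h = rep(90, 60))
  g <- fit_singlet_gate(tb)
  expect_true(all(gate_pass(g, tb)))
  expect_error(fit_singlet_gate(make_table(rep(100, 10))),
               class = "cytofect_insufficient_data_error")
  neg <- make_table(c(rep(-1, 30), rep(100, 30)))
  expect_error(fit_singlet_gate(neg), class = "cytofect_data_error")
})

test_that("singlet gate separates simulated doublets from true singlets", {
  # cell-cell doublets (debris-free mixture): coincidence events pairing a
  # cell with tiny debris keep a near-singlet H/A ratio by construction and
  # are removed later by the intact gate, not by the ratio band
  cfg <- default_sim_config(n_events = 10000, seed = 3,
                            doublet_fraction = 0.10, debris_fraction = 0)
  s <- simulate_sample(cfg)
  g <- fit_singlet_gate(s$events, band_width = 0.15)
  pass <- gate_pass(g, s$events)
  singlet_true <- !s$truth$doublet
  expect_gte(mean(pass[singlet_true]), 0.99)   # recall of true singlets
  expect_lte(mean(pass[!singlet_true]), 0.05)  # doublet leak
})

test_that("intact gate keeps the expected fraction of a clean population", {
  tb <- make_cloud(20000, seed = 5)
  g <- fit_intact_gate(tb, lower_pct = 2, upper_pct = 99.5)
  kept <- mean(gate_pass(g, tb))
  # per-axis survival (0.995 - 0.02), roughly independent axes
  expected <- (0.995 - 0.02)^2
  expect_lt(abs(kept - expected), 3 * sqrt(expected * (1 - expected) / 20000) + 0.005)
})

test_that("intact gate with degenerate axes keeps identical events", {
  tb <- make_table(rep(100, 50))
  w <- testthat::capture_warnings(g <- fit_intact_gate(tb))
  expect_length(w, 2)            # both scatter axes are degenerate
  expect_match(w, "degenerate", all = TRUE)
  expect_true(all(gate_pass(g, tb)))
})

test_that("intact gate with a clean reference removes injected debris", {
  ref <- make_cloud(10000, seed = 6)
  withr::with_seed(7, {
    n_debris <- 1000
    fsc_d <- rlnorm(n_debris, log(0.05 * 5e4), 0.4)
    debris <- make_table(fsc_a = fsc_d,
                         fsc_h = 0.95 * fsc_d,
                         ssc_a = rlnorm(n_debris, log(0.1 * 3e4), 0.5))
  })
  sample_tb <- make_cloud(9000, seed = 8)
  mixed <- event_table(
    dplyr::bind_rows(tibble::as_tibble(sample_tb), tibble::as_tibble(debris)),
    roles = std_roles)
  g <- fit_intact_gate(mixed, reference = ref)
  pass <- gate_pass(g, mixed)
  is_debris <- c(rep(FALSE, 9000), rep(TRUE, 1000))
  expect_gte(mean(!pass[is_debris]), 0.95)
})

test_that("dye viability threshold behaves as a control percentile", {
  ctrl <- make_cloud(10000, seed = 9)
  # control against itself: dead fraction ~ 1 - pct/100
  g <- viability_gate_dye(ctrl, ctrl, pct = 99.5)
  expect_lt(abs(mean(!gate_pass(g, ctrl)) - 0.005), 0.002)
  # pct = 100: nothing above the maximum
  g100 <- viability_gate_dye(ctrl, ctrl, pct = 100)
  expect_equal(mean(!gate_pass(g100, ctrl)), 0)
})

test_that("dye viability recovers a 20% dye-bright dead fraction", {
  ctrl <- make_cloud(10000, seed = 10)
  withr::with_seed(11, {
    n <- 10000
    dead <- rbinom(n, 1, 0.20) == 1
    via <- ifelse(dead, rlnorm(n, log(50 * 100), 0.4), rlnorm(n, log(50), 0.45))
  })
  tb <- make_table(rep(100, 10000), via = via)
  g <- viability_gate_dye(tb, ctrl, pct = 99.5)
  dead_frac <- mean(!gate_pass(g, tb))
  expect_lt(abs(dead_frac - mean(dead)), 0.02)
})

test_that("scatter viability flags shrunken, granular cells", {
  ref <- make_cloud(10000, seed = 12)
  # sample identical in law to the reference: at most the joint tail mass
  same <- make_cloud(10000, seed = 13)
  g <- viability_gate_scatter(same, ref)
  expect_lte(mean(!gate_pass(g, same)), 0.10)

  # dead cells: FSC shrunk x0.5, SSC inflated x1.6, 25% abundance
  withr::with_seed(14, {
    n <- 12000
    dead <- rbinom(n, 1, 0.25) == 1
    fsc <- ifelse(dead, rlnorm(n, log(0.5 * 5e4), 0.2),
                  rlnorm(n, log(5e4), 0.2))
    ssc <- ifelse(dead, rlnorm(n, log(1.6 * 3e4), 0.3),
                  rlnorm(n, log(3e4), 0.3))
  })
  tb <- make_table(fsc_a = fsc, ssc_a = ssc)
  g2 <- viability_gate_scatter(tb, ref)
  dead_pct <- 100 * mean(!gate_pass(g2, tb))
  expect_lt(abs(dead_pct - 25), 5)
})

test_that("hierarchy masks are nested and match brute-force predicates", {
  cfg <- default_sim_config(n_events = 1000, seed = 15)
  s <- simulate_sample(cfg)
  ctl <- simulate_controls(cfg)
  sg <- fit_singlet_gate(s$events)
  ig <- fit_intact_gate(s$events, reference = ctl$untransfected)
  vg <- viability_gate_dye(s$events, ctl$untransfected)
  res <- apply_hierarchy(s$events, sg, ig, vg)

  # nesting: viable => intact => singlet
  expect_true(all(res$masks$intact[res$masks$viable]))
  expect_true(all(res$masks$singlet[res$masks$intact]))

  # independent per-event re-evaluation of each gate predicate
  df <- as.data.frame(s$events, check.names = FALSE)
  m <- sg$params$center; w <- sg$params$width
  brute_singlet <- vapply(seq_len(nrow(df)), function(i) {
    a <- df[["FSC-A"]][i]; h <- df[["FSC-H"]][i]
    a > 0 && h / a >= m * (1 - w) && h / a <= m * (1 + w)
  }, logical(1))
  brute_intact <- brute_singlet & vapply(seq_len(nrow(df)), function(i) {
    a <- df[["FSC-A"]][i]; ss <- df[["SSC-A"]][i]
    a >= ig$params$fsc_a_lo && a <= ig$params$fsc_a_hi &&
      ss >= ig$params$ssc_a_lo && ss <= ig$params$ssc_a_hi
  }, logical(1))
  brute_viable <- brute_intact &
    vapply(df[["7AAD-A"]], function(v) v <= vg$params$threshold, logical(1))
  expect_identical(res$masks$singlet, brute_singlet)
  expect_identical(res$masks$intact, brute_intact)
  expect_identical(res$masks$viable, brute_viable)

  # counts consistent with masks
  expect_equal(unname(res$counts[c("singlet", "intact", "viable")]),
               c(sum(brute_singlet), sum(brute_intact), sum(brute_viable)))
})

test_that("hierarchy handles all-pass gates and empty tables", {
  tb <- make_table(rep(100, 60), fsc_h = rep(95, 60))
  sg <- fit_singlet_gate(tb)
  ig <- suppressWarnings(fit_intact_gate(tb))
  res <- apply_hierarchy(tb, sg, ig)
  expect_true(all(res$masks$viable))
  expect_equal(unname(res$counts[["viable"]]), 60)

  empty <- make_table(numeric(0))
  res0 <- apply_hierarchy(empty, sg, ig)
  expect_equal(nrow(res0$masks), 0)
  expect_true(all(is.na(res0$fractions)))
})

test_that("gate_sample auto-selects scatter viability without a dye channel", {
  cfg <- default_sim_config(n_events = 5000, seed = 16,
                            include_viability_dye = FALSE)
  s <- simulate_sample(cfg)
  ctl <- simulate_controls(cfg)
  res <- gate_sample(s$events, reference = ctl$untransfected)
  expect_equal(res$viability_method, "scatter")
  cfg2 <- default_sim_config(n_events = 5000, seed = 16)
  s2 <- simulate_sample(cfg2)
  ctl2 <- simulate_controls(cfg2)
  res2 <- gate_sample(s2$events, reference = ctl2$untransfected)
  expect_equal(res2$viability_method, "dye")
})

test_that("gates are deterministic given table and parameters", {
  tb <- make_cloud(2000, seed = 17)
  g1 <- fit_intact_gate(tb)
  g2 <- fit_intact_gate(tb)
  expect_identical(g1, g2)
  expect_identical(gate_pass(g1, tb), gate_pass(g2, tb))
})
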