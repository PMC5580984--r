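test_that("positivity threshold is an interpolated control percentile", {
  ctrl <- make_table(rep(100, 1000), dna = 1:1000)
  # 99.9th percentile of 1..1000 by linear interpolation between order stats
  expect_equal(suppressWarnings(positivity_threshold(ctrl, "dna_label", 99.9)),
               999.001)
  sym <- make_table(rep(100, 1000), dna = c(1:500, 501:1000))
  expect_equal(suppressWarnings(positivity_threshold(sym, "dna_label", 50)),
               median(1:1000))
  const <- make_table(rep(100, 300), dna = 7)
  expect_equal(positivity_threshold(const, "dna_label", 99.9), 7)
  expect_error(positivity_threshold(make_table(numeric(0)), "dna_label"),
               class = "cytofect_insufficient_data_error")
  expect_warning(positivity_threshold(make_table(rep(1, 50), dna = 1),
                                      "dna_label"),
                 class = "cytofect_warning")
})

test_that("quadrant percentages follow the tie rule and close to 100", {
  tb <- make_table(rep(100, 4), dna = c(10, 10, 1, 1),
                   protein = c(1, 10, 10, 1))
  q <- quadrant_stats(tb, x_threshold = 5, y_threshold = 5)
  expect_equal(unname(q$pct), c(25, 25, 25, 25))
  expect_equal(sum(q$pct), 100)

  # events exactly at the thresholds fall on the non-positive side
  ties <- make_table(rep(100, 5), dna = 5, protein = 5)
  qt <- quadrant_stats(ties, 5, 5)
  expect_equal(unname(qt$pct[["Q4"]]), 100)

  # empty table: undefined sentinel
  q0 <- quadrant_stats(make_table(numeric(0)), 5, 5)
  expect_true(all(is.na(q0$pct)))
})

test_that("quadrants equal brute-force counts on simulated data", {
  cfg <- default_sim_config(n_events = 10000, seed = 21,
                            protein_only_fraction = 0.15)
  s <- simulate_sample(cfg)
  x <- role_values(s$events, "dna_label")
  y <- role_values(s$events, "protein")
  tx <- 400; ty <- 300
  q <- quadrant_stats(s$events, tx, ty)
  n <- n_events(s$events)
  brute <- c(Q1 = sum(x > tx & y <= ty), Q2 = sum(x > tx & y > ty),
             Q3 = sum(x <= tx & y > ty), Q4 = sum(x <= tx & y <= ty))
  expect_equal(q$pct, 100 * brute / n)
  expect_equal(sum(q$pct), 100)
})

test_that("blank-corrected MFI subtracts the matched control median", {
  a <- make_table(rep(100, 101), dna = seq(400, 600))   # median 500
  b <- make_table(rep(100, 101), dna = seq(20, 220))    # median 120
  expect_equal(blank_corrected_mfi(a, b, "dna_label"), 380)
  expect_equal(blank_corrected_mfi(a, a, "dna_label"), 0)
  expect_warning(v <- blank_corrected_mfi(b, a, "dna_label"),
                 class = "cytofect_warning")
  expect_equal(v, -380)
  expect_error(blank_corrected_mfi(a, make_table(numeric(0)), "dna_label"),
               class = "cytofect_insufficient_data_error")
})

test_that("transfected fraction is recovered by pct_dna_pos", {
  cfg <- default_sim_config(n_events = 20000, seed = 22,
                            transfected_fraction = 0.30)
  s <- simulate_sample(cfg)
  ctl <- simulate_controls(cfg)
  tr <- transfection_readouts(s$events, ctl)
  expect_lt(abs(tr$pct_dna_pos - 30), 2)
  expect_equal(tr$pct_dna_pos,
               unname(tr$quadrants$pct[["Q1"]] + tr$quadrants$pct[["Q2"]]))
  expect_equal(tr$pct_protein_pos,
               unname(tr$quadrants$pct[["Q2"]] + tr$quadrants$pct[["Q3"]]))
})

test_that("running a control as the sample gives a null readout", {
  cfg <- default_sim_config(n_events = 10000, seed = 23)
  ctl <- simulate_controls(cfg)
  un <- ctl$untransfected
  attr(un, "sample_id") <- "untransfected_as_sample"
  # near-zero blank corrections may dip below zero and warn; that is the
  # expected null behavior, not a test failure
  tr <- suppressWarnings(transfection_readouts(un, ctl))
  expect_lte(tr$pct_dna_pos, 0.5)
  # DNA blank: untransfected autofluorescence vs unlabeled-plasmid control
  expect_lt(abs(tr$dmfi_dna), 12)
  expect_lt(abs(tr$dmfi_protein), 12)
})

test_that("a protein+/DNA- subpopulation moves only the protein readout", {
  cfg <- default_sim_config(n_events = 20000, seed = 24,
                            transfected_fraction = 0.45,
                            protein_only_fraction = 0.15)
  s <- simulate_sample(cfg)
  ctl <- simulate_controls(cfg)
  tr <- transfection_readouts(s$events, ctl)
  expect_lt(abs(unname(tr$quadrants$pct[["Q3"]]) - 15), 3)
  expect_lt(abs(tr$pct_dna_pos - 45), 2)
  expect_lt(abs(tr$pct_protein_pos - 60), 3)
})

test_that("missing controls raise a configuration error naming the control", {
  cfg <- default_sim_config(n_events = 2000, seed = 25)
  s <- simulate_sample(cfg)
  expect_error(transfection_readouts(s$events, list(untransfected = NULL)),
               class = "cytofect_config_error")
})

test_that("toxicity readout is null when sample equals the control", {
  cfg <- default_sim_config(n_events = 10000, seed = 26)
  ctl <- simulate_controls(cfg)
  un <- ctl$untransfected
  tox <- toxicity_readout(un, un)
  expect_lt(abs(tox$excess_death), 1e-9)
})

test_that("toxicity recovers a 20% dye-positive dead fraction", {
  # dead cells differ only in dye uptake, isolating the dye accounting
  ctrl <- make_cloud(10000, seed = 27)
  withr::with_seed(28, {
    n <- 20000
    dead <- rbinom(n, 1, 0.20) == 1
    fsc <- rlnorm(n, log(5e4), 0.2)
    tb <- make_table(fsc_a = fsc, fsc_h = 0.95 * fsc * (1 + rnorm(n, 0, 0.02)),
                     ssc_a = rlnorm(n, log(3e4), 0.3),
                     dna = rlnorm(n, log(100), 0.5),
                     protein = rlnorm(n, log(80), 0.5),
                     via = ifelse(dead, rlnorm(n, log(5000), 0.4),
                                  rlnorm(n, log(50), 0.45)))
  })
  tox <- toxicity_readout(tb, ctrl)
  expect_lt(abs(tox$pct_dead - 20), 2)
  expect_equal(tox$method, "dye")
})

test_that("death concentrated in DNA+ cells raises pct_dead_among_dna_pos", {
  ctrl <- make_cloud(10000, seed = 29)
  withr::with_seed(30, {
    n <- 20000
    dna_pos <- rbinom(n, 1, 0.4) == 1
    dead <- dna_pos & rbinom(n, 1, 0.3) == 1   # death only among DNA+
    fsc <- rlnorm(n, log(5e4), 0.2)
    tb <- make_table(fsc_a = fsc, fsc_h = 0.95 * fsc * (1 + rnorm(n, 0, 0.02)),
                     ssc_a = rlnorm(n, log(3e4), 0.3),
                     dna = ifelse(dna_pos, rlnorm(n, log(8000), 0.5),
                                  rlnorm(n, log(50), 0.5)),
                     via = ifelse(dead, rlnorm(n, log(5000), 0.4),
                                  rlnorm(n, log(50), 0.45)))
  })
  tox <- toxicity_readout(tb, ctrl)
  expect_gt(tox$pct_dead_among_dna_pos, tox$pct_dead)
  # brute-force check of the conditional percentage
  expect_lt(abs(tox$pct_dead_among_dna_pos - 30), 3)
})

test_that("increasing DNA brightness never decreases pct_dna_pos", {
  shifts <- c(30, 90, 180, 400)
  res <- vapply(shifts, function(sh) {
    cfg <- default_sim_config(n_events = 8000, seed = 31, dna_shift = sh,
                              transfected_fraction = 0.5)
    s <- simulate_sample(cfg)
    ctl <- simulate_controls(cfg)
    transfection_readouts(s$events, ctl)$pct_dna_pos
  }, numeric(1))
  expect_true(all(diff(res) >= -0.25))  # monotone up to binomial jitter
})
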