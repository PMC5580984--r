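# fixtures built in code: small event tables with standard roles

std_roles <- c("FSC-A" = "fsc_a", "FSC-H" = "fsc_h", "SSC-A" = "ssc_a",
               "FITC-A" = "dna_label", "mCherry-A" = "protein",
               "7AAD-A" = "viability")

# build an event table from per-channel vectors (recycled to equal length)
make_table <- function(fsc_a, fsc_h = fsc_a * 0.95, ssc_a = fsc_a * 0.6,
                       dna = 100, protein = 80, via = 50,
                       sample_id = "fixture", timepoint_h = NULL) {
  n <- max(lengths(list(fsc_a, fsc_h, ssc_a, dna, protein, via)))
  df <- tibble::tibble(
    "FSC-A" = rep_len(fsc_a, n), "FSC-H" = rep_len(fsc_h, n),
    "SSC-A" = rep_len(ssc_a, n), "FITC-A" = rep_len(dna, n),
    "mCherry-A" = rep_len(protein, n), "7AAD-A" = rep_len(via, n)
  )
  event_table(df, roles = std_roles, sample_id = sample_id,
              timepoint_h = timepoint_h)
}

# a well-behaved lognormal cell cloud (no dead cells, no debris)
make_cloud <- function(n, seed = 1, dna = 100, protein = 80, via = 50) {
  withr::with_seed(seed, {
    fsc <- rlnorm(n, log(5e4), 0.2)
    make_table(fsc_a = fsc, fsc_h = 0.95 * fsc * (1 + rnorm(n, 0, 0.02)),
               ssc_a = rlnorm(n, log(3e4), 0.3),
               dna = rlnorm(n, log(dna), 0.5),
               protein = rlnorm(n, log(protein), 0.5),
               via = rlnorm(n, log(via), 0.45))
  })
}
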