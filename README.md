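# cytofect

Quantitative flow-cytometric analysis of transfection efficiency.

## The problem

The usual currency of transfection experiments — "percent of cells
expressing the reporter" — conflates delivery, expression and toxicity,
and GFP co-transfection reporters add their own artifacts. A more direct
design labels the plasmid itself with a fluorochrome (about one label per
40 bp of double-stranded DNA) and reads **two independent signals per
cell** on non-overlapping detectors:

* **uptake** — fluorescence of the labeled plasmid (FITC channel), and
* **expression** — the encoded protein (fluorescent protein or labeled
  antibody),

while a third channel (or scatter alone, for electroporation) quantifies
cell death. cytofect implements the complete analysis for that assay:

* the gating hierarchy — singlets by the FSC-H/FSC-A pulse ratio, intact
  cells by an FSC-A × SSC-A percentile box, viable cells by dye threshold
  or a scatter dead-region;
* control-anchored statistics — positivity thresholds at the 99.9th
  percentile of the matched negative control, quadrant percentages
  (`%DNA+ = Q1+Q2`, `%protein+ = Q2+Q3`), blank-corrected median
  fluorescence ΔMFI = median(sample) − median(control);
* **MESF standardization** — a log–log standard curve
  `log10(MESF) = a + b·log10(MFI)` fitted to calibration-bead peaks
  converts ΔMFI into absolute fluorochrome counts, and the labeling
  density turns those into **plasmid copies (and moles) per cell**:
  `copies = MESF / (length_bp / bp_per_label)`;
* toxicity readouts, time-course peak finding, control normalization,
  inter-assay CVs, Spearman correlations and nonparametric group
  comparisons;
* a seeded synthetic cytometry simulator with per-event ground truth, and
  FCS 3.0/3.1 + CSV event I/O, so the whole pipeline is testable end to
  end without instrument data.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate a transfection experiment (60% of viable cells transfected,
12% dead cells, harvested 24 h post transfection), calibrate simulated
MESF beads, and compute the per-sample readouts:

```r
library(cytofect)

cfg   <- default_sim_config(n_events = 20000, seed = 7)
s     <- simulate_sample(cfg)
ctl   <- simulate_controls(cfg)

beads <- simulate_beads(true_slope = 1, true_intercept = 2,
                        cv_per_peak = 0.08, seed = 7)
cal   <- calibrate_beads(beads)
cal
#> <MESF bead calibration>
#>   log10(MESF) = 2.0014 + 0.9995 * log10(MFI), r2 = 1.0000
#>   valid MFI range: [50.09, 1.278e+04] (5 peaks)

tr <- transfection_readouts(s$events, ctl, calibration = cal,
                            plasmid = plasmid_spec("pUltraHot", 8314))
tr
#> <transfection readout: sim_sample @ 24 h>
#>   DNA+ 59.53%  protein+ 59.57%  (n viable = 14867, viability by dye)
#>   dMFI: DNA 4194, protein 2213
#>   MESF(DNA) 4.189e+05  -> 2015 plasmid copies/cell

toxicity_readout(s$events, ctl$untransfected)
#> <toxicity readout: sim_sample (by dye)>
#>   dead 6.26% (control 0.21%, excess 6.05)
#>   dead among DNA+ events: 0.05%
```

Reading the output: 59.5% of viable cells carry detectable labeled
plasmid and 59.6% express the protein (the true simulated fraction is
60%). The blank-corrected FITC median of 4194 units converts through the
bead curve to ~4.2×10⁵ MESF, i.e. ~2015 copies of the 8314 bp plasmid per
cell at 207.85 labels per plasmid. Toxicity among intact singlets is 6.3%
versus 0.2% in the untransfected control. `tidy(tr)` returns the same
readout as a one-row tibble for binding across samples; `run_pipeline()`
drives a whole manifest (samples, controls, assays, timepoints) from a
YAML/JSON config and writes `report.json` + `readouts.csv`, and
`inst/cli/cytofect` exposes `run` / `simulate` / `calibrate` subcommands
for shell use.

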