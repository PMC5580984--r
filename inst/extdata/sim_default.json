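{
  "version": "1.0",
  "description": "Default distribution parameters for the cytofect synthetic cytometry simulator. Scatter and autofluorescence values are in acquisition-scale detector units typical of a conventional analyzer; kinetics emulate chemical transfection of an adherent cell line (uptake peaking at 12 h, protein expression saturating towards 48 h).",
  "scatter": {
    "fsc_median": 50000,
    "fsc_sdlog": 0.22,
    "ssc_median": 30000,
    "ssc_sdlog": 0.30,
    "h_ratio": 0.95,
    "h_noise_sd": 0.03
  },
  "fluor": {
    "dna_autofluor": 80,
    "dna_sdlog": 0.50,
    "dna_sdlog_bright": 0.60,
    "protein_autofluor": 60,
    "protein_sdlog": 0.50,
    "protein_sdlog_bright": 0.70,
    "dye_viable_median": 60,
    "dye_viable_sdlog": 0.45,
    "dye_dead_median": 8000,
    "dye_dead_sdlog": 0.40
  },
  "signal": {
    "dna_shift": 180,
    "protein_shift": 120
  },
  "dead": {
    "fsc_mult": 0.6,
    "ssc_mult": 1.5
  },
  "debris": {
    "fsc_mult": 0.05,
    "ssc_mult": 0.1,
    "fsc_sdlog": 0.40,
    "ssc_sdlog": 0.50
  },
  "control": {
    "dead_fraction": 0.003,
    "debris_fraction": 0.004,
    "zero_timepoint_h": 3
  },
  "kinetics": {
    "uptake_peak_h": 12,
    "uptake_shape": 2,
    "protein_t50_h": 18,
    "protein_hill": 2
  },
  "beads": {
    "peak_mfis": [50, 200, 800, 3200, 12800],
    "blank_mfi": 6
  }
}
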