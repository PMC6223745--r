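# Example study: two Norway spruce cell lines, dispersed vs non-dispersed
# PEMs, matured in temporary immersion bioreactors. Population parameters
# are field-typical values for mature spruce somatic embryo lengths;
# n_embryos is per replicate.
seed: 1
analysis:
  delta: 1.0
  origin: 0.0
  fractions: [0.50, 0.66, 0.75]
  ci_level: 0.90
  welch: false
groups:
  - label: cl_11_12_02_BR_dispersed
    cell_line: "11:12:02"
    treatment: dispersed
    culture: bioreactor
    n_replicates: 6
    population: {mean_length: 3.05, sd_length: 0.74, n_embryos: 173,
                 between_replicate_sd: 0.10}
    sampled_fraction: 0.15
    initial_fw_g: 2.15
    germination: {p_start: 0.860, p_root_given_start: 0.865,
                  n_collected: 1006}
  - label: cl_11_12_02_BR_non_dispersed
    cell_line: "11:12:02"
    treatment: non_dispersed
    culture: bioreactor
    n_replicates: 6
    population: {mean_length: 2.92, sd_length: 0.77, n_embryos: 196,
                 between_replicate_sd: 0.10}
    sampled_fraction: 0.75
    initial_fw_g: 2.19
    germination: {p_start: 0.928, p_root_given_start: 0.727,
                  n_collected: 994}
  - label: cl_11_12_04_BR_dispersed
    cell_line: "11:12:04"
    treatment: dispersed
    culture: bioreactor
    n_replicates: 5
    population: {mean_length: 2.77, sd_length: 0.87, n_embryos: 145,
                 between_replicate_sd: 0.10}
    sampled_fraction: 0.18
    initial_fw_g: 2.15
    germination: {p_start: 0.562, p_root_given_start: 0.891,
                  n_collected: 605}
  - label: cl_11_12_04_BR_non_dispersed
    cell_line: "11:12:04"
    treatment: non_dispersed
    culture: bioreactor
    n_replicates: 5
    population: {mean_length: 2.73, sd_length: 0.84, n_embryos: 115,
                 between_replicate_sd: 0.10}
    sampled_fraction: 0.59
    initial_fw_g: 2.19
    germination: {p_start: 0.765, p_root_given_start: 0.802,
                  n_collected: 608}
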