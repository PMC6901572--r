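# Baseline P3 experiment: P0-composition initial layouts, vacancy-mediated
# transition probabilities solved from the P3 stage-average area ratios at
# p_VS = 0.6, 100 replicates run to completion.
geometry:
  region_diameter: 300
  site_diameter: 30
  n_sites: 100
  min_separation_factor: 0.8
  neighbor_distance: 37.5
composition:
  init: P0
  n_axons: 9
model:
  variant: vacancy_mediated
  stationary: P3
  p_vs: 0.6
activity:
  n_active: 0
  selection_divisor: 2
execution:
  max_iter: 2000000
  n_reps: 100
  base_seed: 1
  series_stride: 0
output:
  dir: "."
  prefix: "p3"
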