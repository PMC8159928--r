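# Toy end-to-end configuration: 4 x 4 lattice, one year, two seasonal
# wind regimes (westerlies in summer, easterlies in winter).
seed: 42
grid:
  n_rows: 4
  n_cols: 4
  cell_km: 74
  origin: [5.0, 43.0]
duration_h: 48
calendar:
  start: "2015-01-01"
  end: "2015-12-31"
  drop_leap: true
  regimes:
    - {months: [5, 6, 7, 8, 9], bearing_deg: 270, speed_kmh: 40,
       dir_noise_deg: 15, speed_noise_kmh: 5}
    - {months: [10, 11, 12, 1, 2, 3, 4], bearing_deg: 90, speed_kmh: 40,
       dir_noise_deg: 15, speed_noise_kmh: 5}
si:
  threshold: 0.1
  steps: 6
pareto:
  fraction: 0.01
  score: polyline
cluster:
  k: 2
  method: auto
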