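# Demonstration pipeline configuration: simulates four seasons of weather
# and counts, runs feature engineering, Boruta selection, the DLNM, the
# prediction suite and the warning engine.
seed: 11
synthetic:
  years: [2016, 2017, 2018, 2019]
  exposure: tmax
  threshold: 30
  slope: 0.05
boruta:
  max_iter: 25
dlnm:
  exposure: tmax_c
  max_lag: 5
  lag_degree: 2
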