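# Example run configuration for the powerpriornb pipelines.
# Exactly one of `generator` / `datasets` may be present.
label: demo
seed: 42
generator:
  dispersion_r: 2        # well-identified dispersion regime
a0: 1.0                  # used by `fit`
grid: [0.0, 0.25, 0.5, 0.75, 1.0]   # used by `sweep`
prior:
  coef_mean: 0
  coef_variance: 1.0e6
chains:
  n_chains: 4
  n_iterations: 8000
  burn_in: 2000
offset: false
# datasets:
#   historical: path/to/historical.csv
#   current: path/to/current.csv
#   mapping: {tes: score}
#   delim: ","
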