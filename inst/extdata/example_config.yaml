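# Example run configuration for the ppas command line.
# Any key from ppas_defaults() may be overridden here; flags override the
# file, which overrides the defaults.
scenario:
  product_type: liquid
  amount: 200          # mL of product spread in the chamber
  plateau_ppbv: 1160
  rise_rate: 1.0       # per hour
  duration_h: 3
  seed: 1
deployment_times: [0.5, 1.0, 2.0]
n_replicates: 3
noise_cv: 0.05
seed: 1
out_dir: runs/example
sampler:
  K_SA: 10             # assumed partition constant, flagged in reports
gas:
  temperature: 298.15  # K
  pressure: 101325     # Pa
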