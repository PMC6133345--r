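# Example availbias pipeline configuration: every key is optional and
# overrides the defaults of read_pipeline_config().
output_dir: blue_shark_run
seed: 7
paths:
  tags: null        # CSV of depth-bin records; null -> sim-tags output
  effort: null      # CSV of GPS fixes (lon, lat, on_effort, covariates)
  sightings: null   # CSV of sightings (distance, species, covariates)
  grid: null        # CSV environmental grid (lon, lat, covariates, area)
burn_in_days: 2
shelf_threshold: 175        # dive-rule changepoint depth, metres
mcmc:
  n_iter: 5000
  n_burn: 1000
  n_chains: 3
detection:
  w: 500                    # truncation distance, metres
  key: hazard_rate
  candidate_covariates:
    - []                    # null model
    - [cloud]
segment_length_km: 10
dsm_covariates: [dist_200m_km]
average_availability: null  # null -> pooled tag mean, rounded to 2 dp
scenarios: [uncorrected, average, modelled]
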