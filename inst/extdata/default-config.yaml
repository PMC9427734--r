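# Default scenario configuration. Every model constant appears here; values
# are the package defaults (see ?scenario_config).
scenario: BAU            # BAU | 10pc | 50pc | 90pc  (PR = 0 / 0.1 / 0.5 / 0.9)
ssp: SSP2                # SSP1 | SSP2 | SSP3
seed: 0
n_regions: 12
years: [2020, 2100]      # annual timestep
half_lives:
  roundwood: 35          # years, industrial roundwood HWP pool
  engineered: 60         # years, engineered wood in buildings
CW: ~                    # carbon-to-wood ratio override (tC/tDM); null uses
                         # the regional draws around the 0.476 global mean
harvest_efficiency: 0.5  # engineered-wood harvesting efficiency
rotation_rule: CAI       # CAI | MAI
weight_exponent: 1       # sliding-scale annualisation weight exponent
degradation_rate: 0.001  # annual unprotected natural-forest degradation
rw_plantation_share: 0.34
report_every: 5          # land-area reporting interval (years)
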