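# Default NLM coefficients. These are representative values from the
# published nitrogen-loading-model literature (per-capita wastewater
# output, septic plume transmission, land-cover deposition retention,
# fertilizer leaching, livestock excretion); site-specific calibrations
# should override them with a local parameter file.
per_capita_n: 4.8          # kg N person^-1 yr^-1 in wastewater
septic_transmission: 0.46  # fraction of septic N reaching receiving waters
sewered_loss: 0.90         # fraction of sewered N removed by treatment
fertilizer_leaching: 0.39  # fraction of net fertilizer surplus exported
deposition_retention:      # fraction of deposition retained, by cover
  cultivated: 0.62
  natural: 0.89
  impervious: 0.10
  wetland: 0.90
livestock_excretion:       # kg N head^-1 yr^-1
  dairy: 100
  other: 55
livestock_loss:            # fraction of excreted N retained on site
  dairy: 0.80              # retention-pond capture at the dairy
  other: 0.60
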