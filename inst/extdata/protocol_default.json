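{
  "dilution_rate": 0.1,
  "cs_chem_gL": 36.2146646255087,
  "biomass_gdw_L": 10.5,
  "biomass_volume_fraction": 0.002,
  "vacuole_fraction": 0.1,
  "cycle_length": 400,
  "feed_window": 20,
  "feed_multiplier": 20,
  "outflow_end": 260,
  "n_cycles": 20,
  "residence_pre": 5,
  "broth_volume_L": 1,
  "label_fraction": 0.99
}
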