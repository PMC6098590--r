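# Example run configuration for the reference setting.
# Omitted keys fall back to the defaults in oxy_defaults().
population:
  annual_births: 49074
  literacy_rate: 0.67
  growth_rate: 0.03
access:
  p_access: 0.5          # pin the facility-delivery fraction directly
demand:
  pph_rate: 0.02
  extra_doses_per_pph: 4
supply:
  annual_doses: 26500
  shipments_per_year: 2
temperature:
  constant: 25
scenario:
  horizon_years: 30
  birth_decline_per_year: 0.0
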