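# Example semifield (tunnel) scenario: dimethoate-type spray at
# 0.4 kg a.i./ha on a confined Phacelia crop, followed by relocation to
# an untreated monitoring site. Synthetic weather; representative
# toxicology (see ?dimethoate_profile).
simulation:
  start_day: 208
  duration: 55
weather_csv: weather_2012.csv
landscape_phases:
- switch_day: 208
  patches_csv: patches_tunnel.csv
- switch_day: 220
  patches_csv: patches_monitoring.csv
colony:
  eggs: 3000
  larvae: 5000
  pupae: 7000
  adults: 8000
  honey_kJ: 50000
  pollen_g: 250
pesticide:
  name: dimethoate-like
  rud_nectar: 4.4
  rud_pollen: 12.6
  rud_contact_foliar: 14.0
  dt50_plant: 3.0
  knockdown: false
  dose_responses:
  - endpoint: acute_oral
    ld50: 0.1
    slope: 2.5
  - endpoint: contact
    ld50: 0.12
    slope: 2.5
  - endpoint: chronic_oral
    ld50: 0.25
    slope: 2.0
    test_duration_days: 10
  - endpoint: larval
    ld50: 1.5
    slope: 2.0
    test_duration_days: 7
applications:
- day: 212
  rate_kg_per_ha: 0.4
options:
  water_module_on: false
  filter_on: false
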