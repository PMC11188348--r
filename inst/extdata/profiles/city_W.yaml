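# Archetype "W": moderate-pollution city, composite air-quality index 3.04.
schema_version: 1
name: W
target_composite_index: 3.04
pollutant_means: {pm25: 34.048, pm10: 59.584, no2: 26.752, o3: 87.552}
pollutant_cv: 0.25
pm25_pm10_cor: 0.8
water:
  heavy_metal: {mean: 0.035, cv: 0.30}
  dissolved_oxygen: {mean: 7.5, cv: 0.10}
  ph: {mean: 7.4, sd: 0.3}
soil:
  organic_matter: {mean: 3.0, cv: 0.15}
  n_p: {mean: 600, cv: 0.15}
noise: {mean: 64, sd: 5}
thermal:
  temperature: {mean: 26, sd: 4}
  wind_speed: {mean: 2.5, sd: 1.0}
  relative_humidity: {mean: 70, sd: 10}
# noise loads more heavily than PM2.5 in this archetype
risk: {pm25_weight: 0.62, noise_weight: 0.70, latent_sd: 0.3544}
n_sites: 5
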