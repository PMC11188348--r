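# Archetype "K": relatively clean city, composite air-quality index 2.3.
schema_version: 1
name: K
target_composite_index: 2.3
pollutant_means: {pm25: 25.76, pm10: 45.08, no2: 20.24, o3: 66.24}
pollutant_cv: 0.25
pm25_pm10_cor: 0.8
water:
  heavy_metal: {mean: 0.025, cv: 0.30}
  dissolved_oxygen: {mean: 8.5, cv: 0.10}
  ph: {mean: 7.4, sd: 0.3}
soil:
  organic_matter: {mean: 2.5, cv: 0.15}
  n_p: {mean: 500, cv: 0.15}
noise: {mean: 58, sd: 5}
thermal:
  temperature: {mean: 20, sd: 4}
  wind_speed: {mean: 2.5, sd: 1.0}
  relative_humidity: {mean: 68, sd: 10}
# clean air: noise dominates the latent risk structure
risk: {pm25_weight: 0.45, noise_weight: 0.55, latent_sd: 0.7036}
n_sites: 5
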