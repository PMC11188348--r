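# Archetype "B": heavy-pollution city, composite air-quality index 3.92.
# Pollutant means allocate the target composite index across the four
# measured pollutants with fixed shares (pm25 .32, pm10 .28, no2 .22,
# o3 .18 of the sum of C_p/S_p against the default standards).
schema_version: 1
name: B
target_composite_index: 3.92
pollutant_means: {pm25: 43.904, pm10: 76.832, no2: 34.496, o3: 112.896}
pollutant_cv: 0.25
pm25_pm10_cor: 0.8
water:
  heavy_metal: {mean: 0.045, cv: 0.30}
  dissolved_oxygen: {mean: 6.5, cv: 0.10}
  ph: {mean: 7.4, sd: 0.3}
soil:
  organic_matter: {mean: 3.5, cv: 0.15}
  n_p: {mean: 700, cv: 0.15}
noise: {mean: 62, sd: 5}
thermal:
  temperature: {mean: 24, sd: 4}
  wind_speed: {mean: 2.5, sd: 1.0}
  relative_humidity: {mean: 55, sd: 10}
# latent-risk loadings on standardized PM2.5 and noise; latent_sd completes
# the linear predictor to approximately unit variance
risk: {pm25_weight: 0.75, noise_weight: 0.62, latent_sd: 0.2304}
n_sites: 5
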