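# Default pollutant grading: breakpoint rows [c_low, c_high, i_low, i_high]
# and composite-index standards s_p, modelled on the Chinese ambient
# air-quality grading (HJ 633 sub-index intervals; GB 3095-2012 secondary
# standards: annual for SO2/NO2/PM10/PM2.5, daily for CO, 8-hour for O3).
# All tables are user-overridable; units are fixed per pollutant.
schema_version: 1
pollutants:
  pm25:
    units: ug/m3
    s_p: 35
    rows:
      - [0, 35, 0, 50]
      - [35, 75, 50, 100]
      - [75, 115, 100, 150]
      - [115, 150, 150, 200]
      - [150, 250, 200, 300]
      - [250, 350, 300, 400]
      - [350, 500, 400, 500]
  pm10:
    units: ug/m3
    s_p: 70
    rows:
      - [0, 50, 0, 50]
      - [50, 150, 50, 100]
      - [150, 250, 100, 150]
      - [250, 350, 150, 200]
      - [350, 420, 200, 300]
      - [420, 500, 300, 400]
      - [500, 600, 400, 500]
  no2:
    units: ug/m3
    s_p: 40
    rows:
      - [0, 40, 0, 50]
      - [40, 80, 50, 100]
      - [80, 180, 100, 150]
      - [180, 280, 150, 200]
      - [280, 565, 200, 300]
      - [565, 750, 300, 400]
      - [750, 940, 400, 500]
  o3:
    units: ug/m3
    s_p: 160
    rows:
      - [0, 100, 0, 50]
      - [100, 160, 50, 100]
      - [160, 215, 100, 150]
      - [215, 265, 150, 200]
      - [265, 800, 200, 300]
  so2:
    units: ug/m3
    s_p: 60
    rows:
      - [0, 50, 0, 50]
      - [50, 150, 50, 100]
      - [150, 475, 100, 150]
      - [475, 800, 150, 200]
      - [800, 1600, 200, 300]
      - [1600, 2100, 300, 400]
      - [2100, 2620, 400, 500]
  co:
    units: mg/m3
    s_p: 4
    rows:
      - [0, 2, 0, 50]
      - [2, 4, 50, 100]
      - [4, 14, 100, 150]
      - [14, 24, 150, 200]
      - [24, 36, 200, 300]
      - [36, 48, 300, 400]
      - [48, 60, 400, 500]
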