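# Model constants for the pasture dairy footprint model.
# Every numeric constant used by the pipeline lives here so that the
# parameter set actually applied in a run can be exported as a manifest.

gwp:
  n2o: 265          # kg CO2eq per kg N2O, 100-yr horizon
  ch4: 28           # kg CO2eq per kg CH4, 100-yr horizon

nitrogen:
  grazing_proportion: 0.83    # fraction of animal-days spent grazing
  excreta_deposition: 1.0     # fraction of excreted N returned to pasture
  tan_fraction: 0.65          # TAN share of excreted N
  tan_ef_grazing: 0.13        # NH3-N emitted per unit TAN deposited at grazing
  frac_leach: 0.24            # FracLEACH, wet climate
  leach_basis: applied        # "applied" (fertilizer + excreta) or "surplus"
  ef_volatilization: 0.01     # indirect N2O-N per kg NH3-N volatilized
  ef_leaching: 0.011          # indirect N2O-N per kg N leached
  milk_n_divisor: 6.38        # milk protein -> N
  cp_factor: 6.25             # N -> crude protein
  meat_n_export: 8            # kg N/ha/yr exported as live weight
  excretion_fraction: 0.84    # share of ingested N excreted (rest to milk/retention)

n2o_response:                 # soil N2O (kg/ha/yr) vs field-N-balance x (kg N/ha)
  intercept: 1.99
  scale: 1.39
  rate: 0.00488

intake:                       # daily DM intake: lw_coef*LW + milk_coef*milk + intercept
  lw_coef: 0.022              # kg DM per kg live weight
  milk_coef: 0.38             # kg DM per kg ECM/day
  intercept: 3.0              # kg DM/day

methane:                      # enteric CH4 yields before calibration
  yield_herbage: 21.6         # g CH4 per kg pasture DM
  yield_concentrate: 14.0     # g CH4 per kg concentrate DM
  percow_min: 60              # plausibility band, kg CH4/cow/yr
  percow_max: 160

supplement:
  dm_per_day: 3.2             # kg DM/cow/day fed in the parlour
  cp_content: 180             # g CP per kg DM (concentrate mix)
  production_ef: 0.2          # kg CO2eq per kg concentrate DM produced

farm:
  irrigation_volume: 4200     # m3/ha/yr
  seed_rate: 25               # kg seed/ha at renovation
  renovation_interval: 3      # years between pasture renovations
  dressings_per_year: 12      # fertilizer split applications
  slurry_per_lu_day: 0.055    # m3 slurry collected per LU per housed day
  manure_storage_per_lu: 105  # kg CO2eq per LU per yr from stored manure

soc:
  herbage_c_content: 0.45     # g C per g DM
  root_c_fraction: 0.25       # below-ground C input as share of above-ground C
  retention_coefficient: 0.41 # share of C input retained as SOC

herd:
  milk_fat_pct: 4.9
  milk_protein_pct: 3.7
  live_weight: 380            # kg
  stocking_rate: 4.7          # LU/ha
  cows: 454
  farm_area: 121              # ha
  replacement_rate: 0.25
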