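transitions:
  p_sound_to_E2:
    kind: triangular
    low: 0.020999999999999998
    mode: 0.029999999999999999
    high: 0.039
  p_E2_to_D1:
    kind: triangular
    low: 0.154
    mode: 0.22
    high: 0.28600000000000003
  p_D1_to_D2D3:
    kind: triangular
    low: 0.19600000000000001
    mode: 0.28000000000000003
    high: 0.36400000000000005
  p_arrest_failure:
    kind: triangular
    low: 0.013999999999999999
    mode: 0.02
    high: 0.026000000000000002
  p_restoration_failure:
    kind: triangular
    low: 0.049000000000000002
    mode: 0.070000000000000007
    high: 0.091000000000000011
  p_crown_failure:
    kind: triangular
    low: 0.041999999999999996
    mode: 0.059999999999999998
    high: 0.078
  p_endo_complication:
    kind: triangular
    low: 0.020999999999999998
    mode: 0.029999999999999999
    high: 0.039
  p_rootfill_failure:
    kind: triangular
    low: 0.055999999999999994
    mode: 0.080000000000000002
    high: 0.10400000000000001
  p_retreat_failure:
    kind: triangular
    low: 0.126
    mode: 0.17999999999999999
    high: 0.23399999999999999
  p_surg_retreat_failure:
    kind: triangular
    low: 0.17499999999999999
    mode: 0.25
    high: 0.32500000000000001
restoration_failures_before_crown: 3
p_repair:
  kind: point
  low: 0.5
  mode: 0.5
  high: 0.5
dentist_accuracy:
  sens_E2:
    kind: triangular
    low: 0.22
    mode: 0.29999999999999999
    high: 0.38
  sens_D1:
    kind: triangular
    low: 0.32000000000000001
    mode: 0.40000000000000002
    high: 0.47999999999999998
  sens_D2D3:
    kind: triangular
    low: 0.56999999999999995
    mode: 0.65000000000000002
    high: 0.72999999999999998
  specificity:
    kind: triangular
    low: 0.96799999999999997
    mode: 0.98199999999999998
    high: 0.99199999999999999
visual_tactile:
  sens_D2D3:
    kind: triangular
    low: 0.25
    mode: 0.34999999999999998
    high: 0.45000000000000001
  specificity:
    kind: point
    low: 0.995
    mode: 0.995
    high: 0.995
ai_accuracy:
  '0.1':
    sens_E2:
      kind: triangular
      low: 0.54843253364718492
      mode: 0.62081952709006172
      high: 0.69320652053293852
    sens_D1:
      kind: triangular
      low: 0.62829594579884129
      mode: 0.70068293924171809
      high: 0.7730699326845949
    sens_D2D3:
      kind: triangular
      low: 0.77720773213085736
      mode: 0.84054635139337452
      high: 0.90388497065589168
    specificity:
      kind: triangular
      low: 0.93439367584767374
      mode: 0.96153879838875256
      high: 0.98868392092983137
  '0.25':
    sens_E2:
      kind: triangular
      low: 0.6359901909261807
      mode: 0.69829425357189312
      high: 0.76059831621760554
    sens_D1:
      kind: triangular
      low: 0.70294114866419855
      mode: 0.76524521130991097
      high: 0.82754927395562339
    sens_D2D3:
      kind: triangular
      low: 0.83768011423293043
      mode: 0.89219616904792876
      high: 0.94671222386292708
    specificity:
      kind: triangular
      low: 0.94876019606685735
      mode: 0.97212421955899952
      high: 0.9954882430511417
  '0.5':
    sens_E2:
      kind: triangular
      low: 0.68423017520163287
      mode: 0.7327526279786436
      high: 0.78127508075565433
    sens_D1:
      kind: triangular
      low: 0.74543807053852573
      mode: 0.79396052331553635
      high: 0.84248297609254696
    sens_D2D3:
      kind: triangular
      low: 0.87271127247254476
      mode: 0.91516841865242915
      high: 0.95762556483231354
    specificity:
      kind: triangular
      low: 0.96206734529533955
      mode: 0.98026326508671857
      high: 0.99845918487809759
  '1':
    sens_E2:
      kind: triangular
      low: 0.71035079303455151
      mode: 0.73978114832826691
      high: 0.76921150362198232
    sens_D1:
      kind: triangular
      low: 0.77038726831317372
      mode: 0.79981762360688913
      high: 0.82924797890060453
    sens_D2D3:
      kind: triangular
      low: 0.89410253800351036
      mode: 0.91985409888551128
      high: 0.94560565976751221
    specificity:
      kind: triangular
      low: 0.97332256940375106
      mode: 0.98435895263889428
      high: 0.9953953358740375
learning_curves:
  sens_E2:
    floor: 0.5
    asymptote: 0.73999999999999999
    rate: 7.0
    width0: 0.080000000000000002
    width_decay: 1.0
  sens_D1:
    floor: 0.59999999999999998
    asymptote: 0.80000000000000004
    rate: 7.0
    width0: 0.080000000000000002
    width_decay: 1.0
  sens_D2D3:
    floor: 0.76000000000000001
    asymptote: 0.92000000000000004
    rate: 7.0
    width0: 0.070000000000000007
    width_decay: 1.0
  specificity:
    floor: 0.94999999999999996
    asymptote: 0.98499999999999999
    rate: 4.0
    width0: 0.029999999999999999
    width_decay: 1.0
costs:
  radiograph_exam:
    kind: point
    low: 2.5
    mode: 2.5
    high: 2.5
  visual_tactile_exam:
    kind: point
    low: 2.5
    mode: 2.5
    high: 2.5
  infiltration:
    kind: point
    low: 70.0
    mode: 70.0
    high: 70.0
  restoration:
    kind: point
    low: 85.0
    mode: 85.0
    high: 85.0
  restoration_repair:
    kind: point
    low: 45.0
    mode: 45.0
    high: 45.0
  restoration_replacement:
    kind: point
    low: 85.0
    mode: 85.0
    high: 85.0
  crown:
    kind: point
    low: 340.0
    mode: 340.0
    high: 340.0
  crown_replacement:
    kind: point
    low: 340.0
    mode: 340.0
    high: 340.0
  root_canal:
    kind: point
    low: 280.0
    mode: 280.0
    high: 280.0
  retreat_nonsurgical:
    kind: point
    low: 330.0
    mode: 330.0
    high: 330.0
  retreat_surgical:
    kind: point
    low: 260.0
    mode: 260.0
    high: 260.0
  extraction:
    kind: point
    low: 80.0
    mode: 80.0
    high: 80.0
  implant_crown:
    kind: point
    low: 1000.0
    mode: 1000.0
    high: 1000.0
  ai_application:
    kind: uniform
    low: 4.0
    mode: 8.0
    high: 12.0
ai_teeth_per_application: 4.0
risk_profiles:
  low:
    label: low
    prevalence:
      sound: 0.90000000000000002
      E2: 0.055
      D1: 0.029999999999999999
      D2D3: 0.014999999999999999
    progression_multiplier: 0.75
  high:
    label: high
    prevalence:
      sound: 0.56000000000000005
      E2: 0.19
      D1: 0.14999999999999999
      D2D3: 0.10000000000000001
    progression_multiplier: 1.45
risk_weights:
  low: 0.5
  high: 0.5
training_fraction_weights:
  '0.1': 0.25
  '0.25': 0.25
  '0.5': 0.25
  '1': 0.25
discount_rate: 0.029999999999999999
fp_advanced_share: 0.20000000000000001
schedule:
  visual_tactile_every_years: 1
  radiograph_every_years: 2
manifest:
  variant: calibrated
  seed: 1
  version: '1'
  provenance:
    ai_application_cost: published
    discount_rate: published
    schedule: published
    horizon_years: published
    p_sound_to_E2: synthetic
    p_E2_to_D1: synthetic
    p_D1_to_D2D3: synthetic
    p_arrest_failure: synthetic
    p_restoration_failure: synthetic
    p_crown_failure: synthetic
    p_endo_complication: synthetic
    p_rootfill_failure: synthetic
    p_retreat_failure: synthetic
    p_surg_retreat_failure: synthetic
    radiograph_exam: synthetic
    visual_tactile_exam: synthetic
    infiltration: synthetic
    restoration: synthetic
    restoration_repair: synthetic
    restoration_replacement: synthetic
    crown: synthetic
    crown_replacement: synthetic
    root_canal: synthetic
    retreat_nonsurgical: synthetic
    retreat_surgical: synthetic
    extraction: synthetic
    implant_crown: synthetic
    dentist_accuracy: synthetic
    ai_accuracy: synthetic
    visual_tactile: synthetic
    risk_profiles: synthetic

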