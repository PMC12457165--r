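version: '1.0'
description: Trait standardization map, directions, scales and success correlations
  for the selection indices
index_weights:
  w_health: 0.02
  w_behavior: 0.324
standardization:
  distraction:
    High: 1
    Above average: 1
    Average: 0
    Less than average: 0
  neck:
    Hard: 2
    Above average: 2
    Average: 1
    Less than average: 0
    Easy: 0
  pace:
    Fast: 2
    Above average: 2
    High average: 2
    Average: 1
    Less than average: 0
  pull:
    Hard: 2
    Above average: 2
    Average: 1
    Defined average: 1
    Less than average: 0
  rating:
    '5': 7
    4+: 6
    '4': 5
    4-: 4
    3+: 3
    '3': 2
    3-: 1
    2+: 0
  soundness:
    Sound: 2
    Above average: 1
    Average: 0
    Less than average: 0
traits:
- trait: distraction
  kind: ordinal_behavior
  direction: negative
  x_max: 1.0
  weight_r: -0.107
  category_group: behavior
  pseudo_h2: 0.177
- trait: neck
  kind: ordinal_behavior
  direction: negative
  x_max: 2.0
  weight_r: -0.108
  category_group: behavior
  pseudo_h2: 0.209
- trait: rating
  kind: ordinal_behavior
  direction: negative
  x_max: 7.0
  weight_r: -0.144
  category_group: behavior
  pseudo_h2: 0.179
- trait: soundness
  kind: ordinal_behavior
  direction: positive
  x_max: 2.0
  weight_r: 0.127
  category_group: behavior
  pseudo_h2: 0.0
- trait: trainability
  kind: ordinal_behavior
  direction: positive
  x_max: 10.0
  weight_r: 0.531
  category_group: behavior
  pseudo_h2: 0.147
- trait: pace
  kind: ordinal_behavior
  direction: neutral
  x_max: 2.0
  optimum: 1.0
  weight_r: 0.02
  category_group: behavior
  pseudo_h2: 0.153
- trait: pull
  kind: ordinal_behavior
  direction: neutral
  x_max: 2.0
  optimum: 1.0
  weight_r: 0.017
  category_group: behavior
  pseudo_h2: 0.066
- trait: base_narrow_mandibular_canines
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.026
  category_group: dental
  pseudo_h2: 0.146
  prevalence: 0.05
- trait: malocclusion_class_i
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.035
  category_group: dental
  pseudo_h2: 0.148
  prevalence: 0.05
- trait: distichiasis
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.032
  category_group: ocular
  pseudo_h2: 0.092
  prevalence: 0.05
- trait: ppm
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.025
  category_group: ocular
  pseudo_h2: 0.142
  prevalence: 0.05
- trait: loose_interphalangeal_collateral_ligaments
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.003
  category_group: neuro_musculoskeletal
  pseudo_h2: 0.109
  prevalence: 0.05
- trait: umbilical_hernia
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.009
  category_group: other
  pseudo_h2: 0.037
  prevalence: 0.05
- trait: histiocytoma
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.036
  category_group: dermal
  pseudo_h2: 0.039
  prevalence: 0.05
- trait: atopic_dermatitis
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.1
  category_group: dermal
  pseudo_h2: 0.044
  prevalence: 0.05
- trait: allergic_dermatitis
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.009
  category_group: dermal
  pseudo_h2: 0.019
  prevalence: 0.05
- trait: alopecia_bridge_of_nose
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.027
  category_group: dermal
  pseudo_h2: 0.022
  prevalence: 0.05
- trait: acral_lick_dermatitis
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.029
  category_group: dermal
  pseudo_h2: 0.046
  prevalence: 0.05
- trait: muzzle_folliculitis
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.009
  category_group: dermal
  pseudo_h2: 0.023
  prevalence: 0.05
- trait: panosteitis
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.02
  category_group: neuro_musculoskeletal
  pseudo_h2: 0.163
  prevalence: 0.05
- trait: oral_papillomatosis
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.02
  category_group: other
  pseudo_h2: 0.089
  prevalence: 0.05
- trait: supernumerary_teeth
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.024
  category_group: dental
  pseudo_h2: 0.0
  prevalence: 0.05
- trait: retained_deciduous_teeth
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.013
  category_group: dental
  pseudo_h2: 0.131
  prevalence: 0.05
- trait: anodontia
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.014
  category_group: dental
  pseudo_h2: 0.247
  prevalence: 0.05
- trait: mandibular_distocclusion
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.105
  category_group: dental
  pseudo_h2: 0.269
  prevalence: 0.05
- trait: mandibular_prognathism
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.031
  category_group: dental
  pseudo_h2: 0.08
  prevalence: 0.05
- trait: mandibular_mesiocclusion
  kind: binary_health
  direction: negative
  x_max: 1.0
  weight_r: -0.047
  category_group: dental
  pseudo_h2: 0.139
  prevalence: 0.05
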