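kind: phantom
geometry:
  r_inner: 0.255
  r_dielectric: 0.84
  r_outer: 1.0985
  r_catheter: 1.32
  slot_width: 1.0
  slot_separation: 3.969686833313306
  tip_to_first_slot: 3.969686833313306
  total_length: 140.0
  tip_length: 0.5
  cap_length: 0.5
domain_radius: 30.0
domain_height: 80.0
tumor_radius: 12.5
input_power: 10.0
frequency: 2450000000.0
ambient_temperature: 25.0
insertion_depth: 46.954530249969956
slot_fill: air
blood:
  density_bl: 920.0
  heat_capacity_bl: 3639.0
  perfusion_rate: 0.0036
  blood_temperature: 37.0
region_materials:
  conductor:
    name: copper
    eps_r: 1.0
    sigma: 0.0
    mu_r: 1.0
    k_thermal: 400.0
    density: 8960.0
    heat_capacity: 385.0
    is_conductor: yes
  coax_dielectric:
    name: coax_dielectric
    eps_r: 2.03
    sigma: 0.0
    mu_r: 1.0
    k_thermal: 0.2
    density: 2200.0
    heat_capacity: 1050.0
    is_conductor: no
  slot:
    name: air
    eps_r: 1.0
    sigma: 0.0
    mu_r: 1.0
    k_thermal: 0.026
    density: 1.2
    heat_capacity: 1005.0
    is_conductor: no
  catheter:
    name: catheter
    eps_r: 2.6
    sigma: 0.0
    mu_r: 1.0
    k_thermal: 0.2
    density: 2200.0
    heat_capacity: 1050.0
    is_conductor: no
  tissue:
    name: phantom_breast
    eps_r: 5.1467
    sigma: 0.137
    mu_r: 1.0
    k_thermal: 0.25
    density: 950.0
    heat_capacity: 2500.0
    is_conductor: no
  tumor:
    name: phantom_tumor
    eps_r: 59.384999999999998
    sigma: 3.156
    mu_r: 1.0
    k_thermal: 0.55
    density: 1000.0
    heat_capacity: 3800.0
    is_conductor: no

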