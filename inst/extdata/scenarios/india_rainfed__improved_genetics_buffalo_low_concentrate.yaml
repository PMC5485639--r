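region: india_rainfed
scenario: improved_genetics_buffalo_low_concentrate
country: India
currency: INR
breed:
  name: buffalo
  mature_weight: 450.0
  birth_weight: 32.0
  potential_peak_milk: 8.0
  lactation_length: 10.0
  milk_fat: 0.07
  age_first_mating: 30.0
  growth_rate_potential: 0.45
min_breeders: 1.0
max_breeders: 3.0
feeds:
  grass:
    name: grass
    dm: 0.25
    me: 8.5
    cp:
    - 0.08
    - 0.08
    - 0.08
    - 0.08
    - 0.08
    - 0.08
    - 0.08
    - 0.08
    - 0.08
    - 0.08
    - 0.08
    - 0.08
    price: 1.0
    monthly_supply:
    - 1636.36363636363626
    - 1472.727272727272748
    - 1472.727272727272748
    - 1800.0
    - 2618.181818181818016
    - 3927.272727272727479
    - 4909.090909090909008
    - 5236.363636363636033
    - 4745.454545454545041
    - 3600.0
    - 2618.181818181818016
    - 1963.63636363636374
    purchasable: no
    carryover: no
  residues:
    name: residues
    dm: 0.9
    me: 7.0
    cp:
    - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.05
    price: 2.0
    monthly_supply:
    - 0.0
    - 0.0
    - 1200.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1800.0
    - 0.0
    - 0.0
    purchasable: yes
    carryover: yes
  bran:
    name: bran
    dm: 0.9
    me: 11.5
    cp:
    - 0.14
    - 0.14
    - 0.14
    - 0.14
    - 0.14
    - 0.14
    - 0.14
    - 0.14
    - 0.14
    - 0.14
    - 0.14
    - 0.14
    price: 12.0
    monthly_supply:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    purchasable: yes
    carryover: yes
ration:
  breeder:
    grass: 9.0
    residues: 5.0
    bran: 1.0
  heifer:
    grass: 6.0
    residues: 1.0
male_sale:
  age: 1.0
cull_age: 108.0
base_mortality: 0.05
milk_price: 40.0
animal_prices:
  male_calf: 500.0
  growing_male: 8000.0
  female_calf: 1000.0
  heifer: 12000.0
  cull: 20000.0
health_mating_cost: 400.0
horizon: 240.0
init_breeders: 2.0
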