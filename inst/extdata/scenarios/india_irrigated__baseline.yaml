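region: india_irrigated
scenario: baseline
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
  straw:
    name: straw
    dm: 0.9
    me: 6.8
    cp:
    - 0.04
    - 0.04
    - 0.04
    - 0.04
    - 0.04
    - 0.04
    - 0.04
    - 0.04
    - 0.04
    - 0.04
    - 0.04
    - 0.04
    price: 5.0
    monthly_supply:
    - 0.0
    - 0.0
    - 0.0
    - 1000.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1500.0
    - 0.0
    purchasable: yes
    carryover: yes
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
    carryover: no
  rice_bran:
    name: rice_bran
    dm: 0.9
    me: 11.5
    cp:
    - 0.13
    - 0.13
    - 0.13
    - 0.13
    - 0.13
    - 0.13
    - 0.13
    - 0.13
    - 0.13
    - 0.13
    - 0.13
    - 0.13
    price: 10.0
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
  good_grass:
    name: good_grass
    dm: 0.25
    me: 8.800000000000001
    cp:
    - 0.12
    - 0.12
    - 0.12
    - 0.12
    - 0.12
    - 0.12
    - 0.12
    - 0.12
    - 0.12
    - 0.12
    - 0.12
    - 0.12
    price: 2.0
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
    carryover: no
ration:
  breeder:
    straw: 4.0
    grass: 8.0
    rice_bran: 1.5
  heifer:
    straw: 3.0
    grass: 4.0
male_sale:
  age: 1.0
cull_age: 108.0
base_mortality: 0.05
milk_price: 40.0
animal_prices:
  male_calf: 500.0
  growing_male: 8000.0
  female_calf: 1500.0
  heifer: 15000.0
  cull: 20000.0
health_mating_cost: 400.0
horizon: 240.0
init_breeders: 2.0
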