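region: ethiopia_mrd
scenario: improved_genetics_concentrate
country: Ethiopia
currency: ETB
breed:
  name: crossbred_ethiopia
  mature_weight: 420.0
  birth_weight: 28.0
  potential_peak_milk: 8.0
  lactation_length: 10.0
  milk_fat: 0.04
  age_first_mating: 24.0
  growth_rate_potential: 0.55
min_breeders: 3.0
max_breeders: 6.0
feeds:
  pasture:
    name: pasture
    dm: 0.3
    me: 8.0
    cp:
    - 0.05
    - 0.05
    - 0.06
    - 0.07
    - 0.09
    - 0.1
    - 0.11
    - 0.11
    - 0.1
    - 0.08
    - 0.07
    - 0.06
    price: 0.0
    monthly_supply:
    - 424.242424242424249
    - 381.818181818181813
    - 381.818181818181813
    - 466.666666666666742
    - 678.787878787878867
    - 1018.18181818181813
    - 1272.727272727272748
    - 1357.575757575757734
    - 1230.303030303030255
    - 933.333333333333485
    - 678.787878787878867
    - 509.090909090909065
    purchasable: no
    carryover: no
  straw:
    name: straw
    dm: 0.9
    me: 6.5
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
    price: 1.5
    monthly_supply:
    - 1600.0
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
    - 2400.0
    purchasable: no
    carryover: yes
  hay:
    name: hay
    dm: 0.85
    me: 8.800000000000001
    cp:
    - 0.16
    - 0.16
    - 0.16
    - 0.16
    - 0.16
    - 0.16
    - 0.16
    - 0.16
    - 0.16
    - 0.16
    - 0.16
    - 0.16
    price: 3.5
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
  noug:
    name: noug
    dm: 0.92
    me: 11.5
    cp:
    - 0.32
    - 0.32
    - 0.32
    - 0.32
    - 0.32
    - 0.32
    - 0.32
    - 0.32
    - 0.32
    - 0.32
    - 0.32
    - 0.32
    price: 6.0
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
  bran:
    name: bran
    dm: 0.9
    me: 11.0
    cp:
    - 0.15
    - 0.15
    - 0.15
    - 0.15
    - 0.15
    - 0.15
    - 0.15
    - 0.15
    - 0.15
    - 0.15
    - 0.15
    - 0.15
    price: 4.0
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
    pasture: 8.0
    straw: 3.0
    hay: 4.0
    noug: 1.5
    bran: 1.5
  heifer:
    pasture: 6.0
    straw: 2.0
    hay: 1.0
male_sale:
  age: 1.0
cull_age: 108.0
base_mortality: 0.1
milk_price: 10.0
animal_prices:
  male_calf: 600.0
  growing_male: 5500.0
  female_calf: 800.0
  heifer: 4000.0
  cull: 5000.0
health_mating_cost: 150.0
horizon: 240.0
init_breeders: 4.0
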