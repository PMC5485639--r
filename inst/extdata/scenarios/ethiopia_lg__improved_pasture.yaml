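region: ethiopia_lg
scenario: improved_pasture
country: Ethiopia
currency: ETB
breed:
  name: zebu
  mature_weight: 350.0
  birth_weight: 22.0
  potential_peak_milk: 4.5
  lactation_length: 8.0
  milk_fat: 0.045
  age_first_mating: 30.0
  growth_rate_potential: 0.35
min_breeders: 15.0
max_breeders: 20.0
feeds:
  pasture:
    name: pasture
    dm: 0.3
    me: 8.0
    cp:
    - 0.11125
    - 0.11125
    - 0.11625
    - 0.12125
    - 0.13125
    - 0.13625
    - 0.14125
    - 0.14125
    - 0.13625
    - 0.12625
    - 0.12125
    - 0.11625
    price: 0.0
    monthly_supply:
    - 5522.727272727272975
    - 4970.454545454545951
    - 4970.454545454545951
    - 6075.000000000001819
    - 8836.363636363636033
    - 13254.545454545455868
    - 16568.181818181819835
    - 17672.727272727272066
    - 16015.909090909091901
    - 12150.000000000003638
    - 8836.363636363636033
    - 6627.272727272727934
    purchasable: no
    carryover: no
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
ration:
  breeder:
    pasture: 12.0
    noug: 0.4
  heifer:
    pasture: 9.0
  growing_male:
    pasture: 9.0
male_sale:
  age: 12.0
  weight: 180.0
cull_age: 108.0
base_mortality: 0.05
milk_price: 10.0
animal_prices:
  male_calf: 600.0
  growing_male: 5500.0
  female_calf: 800.0
  heifer: 4000.0
  cull: 5000.0
health_mating_cost: 150.0
horizon: 240.0
init_breeders: 18.0
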