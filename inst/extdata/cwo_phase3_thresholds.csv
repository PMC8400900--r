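# Chilean Warning Octagon, Phase 3 (2019) limits: one row set for all foods
# (per 100 g) and one for all beverages (per 100 ml); never keyed by SEARO
# category. A rule is evaluated only when its gating added-ingredient flag is
# "yes"; the calorie label applies to products with added sugar or added
# saturated fat, encoded as two energy rows sharing the "energy" label.
# sodium in mg, energy in kcal, other nutrients in g.
scope_key,nutrient,limit,unit,comparator,gate,label
food,total_sugar,10,g,greater_than,added_sugar,sugar
food,saturated_fat,4,g,greater_than,added_sat_fat,sat_fat
food,sodium,400,mg,greater_than,added_sodium,sodium
food,energy,275,kcal,greater_than,added_sugar,energy
food,energy,275,kcal,greater_than,added_sat_fat,energy
beverage,total_sugar,5,g,greater_than,added_sugar,sugar
beverage,saturated_fat,3,g,greater_than,added_sat_fat,sat_fat
beverage,sodium,100,mg,greater_than,added_sodium,sodium
beverage,energy,70,kcal,greater_than,added_sugar,energy
beverage,energy,70,kcal,greater_than,added_sat_fat,energy
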