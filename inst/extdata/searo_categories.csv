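# WHO SEARO food-category registry: 25 categories; codes starting "6" are
# beverages (evaluated per 100 ml as consumed, all others per 100 g).
# required_nutrients lists the panel fields the category-specific SEARO rules
# reference (semicolon-separated); sufficiency additionally requires whatever
# the other requested models reference.
code,name,is_beverage,required_nutrients
1,Confectionary,FALSE,energy;saturated_fat;sodium;total_fat;total_sugar
2,"Cakes, sweet biscuits, pastries",FALSE,energy;saturated_fat;sodium;total_fat;total_sugar
3,Bread and bread products,FALSE,sodium;total_fat;total_sugar
4,Cereals,FALSE,sodium;total_fat;total_sugar
5A,"Potato, cereal, or starch-based (from roots, tuber, or legumes), and animal-based (from skin) foods",FALSE,sodium;total_fat;total_sugar
5B,Processed nuts,FALSE,sodium;total_fat;total_sugar
5C,Fish-based foods,FALSE,sodium;total_fat
6A,Juices,TRUE,total_sugar
6B,Milk- and dairy-based drinks,TRUE,sodium;total_fat;total_sugar
6C,Water-based flavored drinks,TRUE,sodium;total_sugar
6D,"Coffee, coffee substitutes, tea, herbal infusions",TRUE,total_fat;total_sugar
6E,"Cereal, grain, tree nut-based beverages",TRUE,total_fat;total_sugar
7,Frozen dairy-based desserts and edible ices,FALSE,saturated_fat;sodium;total_fat;total_sugar
8,Curded dairy-based desserts,FALSE,saturated_fat;sodium;total_fat;total_sugar
9,Cheese and analogues,FALSE,sodium;total_fat
10,Composite foods (prepared foods),FALSE,energy;saturated_fat;sodium;total_fat;total_sugar
11,"Fats and oils, and fat emulsions",FALSE,saturated_fat;sodium
12,"Pasta, noodles, and similar products",FALSE,sodium;total_fat;total_sugar
13,"Fresh and frozen meat, poultry, game, fish, and seafood products",FALSE,sodium;total_fat
14A,"Processed meat, poultry, and game products",FALSE,sodium;total_fat
14B,Processed fish and seafood products,FALSE,sodium;total_fat
15,"Fresh and frozen fruits and vegetables, and legumes",FALSE,added_sugar;sodium;total_fat
16,Processed fruits and vegetables,FALSE,sodium;total_fat;total_sugar
17,Solid-form soybean products,FALSE,sodium;total_fat;total_sugar
18,"Sauces, dips, and dressings",FALSE,sodium;total_fat;total_sugar
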