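# SEARO nutrient profile model threshold table (RECONSTRUCTED).
# The authoritative per-category limits live in the WHO SEARO NPM publication;
# the values below are a reconstruction from the public WHO regional NPM
# family and are shipped as editable data, not code: replace this file with a
# verbatim transcription to reproduce any given study exactly.
# scope_key is a SEARO category code; limits are per 100 g (foods) or per
# 100 ml (beverages, codes 6A-6E) on an as-consumed basis; sodium in mg,
# energy in kcal, other nutrients in g. comparator greater_than means the
# amount must strictly exceed the limit to earn the label.
scope_key,nutrient,limit,unit,comparator,gate,label
1,total_sugar,6,g,greater_than,,sugar
1,total_fat,9,g,greater_than,,fat
1,saturated_fat,5,g,greater_than,,sat_fat
1,sodium,120,mg,greater_than,,sodium
1,energy,225,kcal,greater_than,,energy
2,total_sugar,6,g,greater_than,,sugar
2,total_fat,9,g,greater_than,,fat
2,saturated_fat,5,g,greater_than,,sat_fat
2,sodium,120,mg,greater_than,,sodium
2,energy,225,kcal,greater_than,,energy
3,total_fat,10,g,greater_than,,fat
3,total_sugar,10,g,greater_than,,sugar
3,sodium,480,mg,greater_than,,sodium
4,total_fat,10,g,greater_than,,fat
4,total_sugar,15,g,greater_than,,sugar
4,sodium,640,mg,greater_than,,sodium
5A,total_fat,10,g,greater_than,,fat
5A,total_sugar,10,g,greater_than,,sugar
5A,sodium,40,mg,greater_than,,sodium
5B,total_fat,20,g,greater_than,,fat
5B,total_sugar,10,g,greater_than,,sugar
5B,sodium,40,mg,greater_than,,sodium
5C,total_fat,10,g,greater_than,,fat
5C,sodium,480,mg,greater_than,,sodium
6A,total_sugar,5,g,greater_than,,sugar
6B,total_fat,2.5,g,greater_than,,fat
6B,total_sugar,9,g,greater_than,,sugar
6B,sodium,120,mg,greater_than,,sodium
6C,total_sugar,2,g,greater_than,,sugar
6C,sodium,100,mg,greater_than,,sodium
6D,total_fat,2.5,g,greater_than,,fat
6D,total_sugar,2,g,greater_than,,sugar
6E,total_fat,2.5,g,greater_than,,fat
6E,total_sugar,6,g,greater_than,,sugar
7,total_fat,5,g,greater_than,,fat
7,saturated_fat,2.5,g,greater_than,,sat_fat
7,total_sugar,10,g,greater_than,,sugar
7,sodium,120,mg,greater_than,,sodium
8,total_fat,2.5,g,greater_than,,fat
8,saturated_fat,2,g,greater_than,,sat_fat
8,total_sugar,10,g,greater_than,,sugar
8,sodium,80,mg,greater_than,,sodium
9,total_fat,20,g,greater_than,,fat
9,sodium,520,mg,greater_than,,sodium
10,total_fat,10,g,greater_than,,fat
10,saturated_fat,4,g,greater_than,,sat_fat
10,total_sugar,10,g,greater_than,,sugar
10,sodium,400,mg,greater_than,,sodium
10,energy,225,kcal,greater_than,,energy
11,saturated_fat,20,g,greater_than,,sat_fat
11,sodium,520,mg,greater_than,,sodium
12,total_fat,10,g,greater_than,,fat
12,total_sugar,10,g,greater_than,,sugar
12,sodium,480,mg,greater_than,,sodium
13,total_fat,10,g,greater_than,,fat
13,sodium,520,mg,greater_than,,sodium
14A,total_fat,20,g,greater_than,,fat
14A,sodium,680,mg,greater_than,,sodium
14B,total_fat,20,g,greater_than,,fat
14B,sodium,680,mg,greater_than,,sodium
15,added_sugar,0,g,greater_than,,sugar
15,total_fat,5,g,greater_than,,fat
15,sodium,200,mg,greater_than,,sodium
16,total_fat,5,g,greater_than,,fat
16,total_sugar,15,g,greater_than,,sugar
16,sodium,400,mg,greater_than,,sodium
17,total_fat,10,g,greater_than,,fat
17,total_sugar,10,g,greater_than,,sugar
17,sodium,400,mg,greater_than,,sodium
18,total_fat,10,g,greater_than,,fat
18,total_sugar,10,g,greater_than,,sugar
18,sodium,400,mg,greater_than,,sodium
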