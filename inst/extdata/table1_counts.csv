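# Published per-category counts and coverage for the 2015-2020 Indian
# packaged-food sample: products assigned to each SEARO category (total_n),
# products with sufficient as-consumed nutrient information (n_evaluable), and
# the number/percent meeting at least one SEARO or CWO Phase 3 criterion.
# Used as the default category mix and calibration target for the synthetic
# generator, and as planted counts in report-arithmetic tests.
category_code,total_n,n_evaluable,searo_n,searo_pct,cwo_n,cwo_pct
1,3148,1377,1368,99.3,1333,96.8
2,2669,667,667,100,666,99.8
3,1050,184,123,66.8,109,59.2
4,2619,1008,377,37.4,413,40.9
5A,4092,1312,1312,100,1285,97.9
5B,1022,478,454,94.9,249,52.1
5C,4,0,NA,NA,NA,NA
6A,517,235,180,76.5,124,52.7
6B,905,228,169,74.1,80,35.0
6C,2123,783,691,88.2,583,74.4
6D,1883,1418,132,9.3,69,4.8
6E,249,155,61,39.3,55,35.4
7,595,128,123,96.0,118,92.1
8,426,111,105,94.5,102,91.8
9,626,200,178,89,129,64.5
10,1219,160,114,71.2,86,53.7
11,1715,204,84,41.1,21,10.2
12,630,9,3,33.3,3,33.3
13,20,20,4,20,0,0
14A,466,61,59,96.7,47,77.0
14B,216,61,43,70.4,31,50.8
15,89,14,0,0,0,0
16,2448,849,255,30.0,520,61.2
17,86,6,1,16.6,0,0
18,2702,833,682,81.8,600,72.0
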