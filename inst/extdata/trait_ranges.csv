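si,trait,min_core,max_core,min_panel,max_panel,mean_core,mean_panel,p_value,var_core,var_panel
1,ear_head_emergence_days,45.0,79.0,45.0,79.0,59.9,60.3,0.27,39.9,40.2
2,plant_height_cm,45.0,146.0,45.0,146.0,94.4,95.5,0.34,278.6,329.2
3,productive_tiller_per_plant,1.4,8.4,1.4,8.4,3.9,4.0,0.15,1.3,1.6
4,unproductive_tiller_per_plant,0.1,2.0,0.1,2.0,0.5,0.5,0.12,0.1,0.1
5,productive_tiller_ratio_pct,60.0,100.0,60.0,100.0,90.4,90.0,0.44,48.5,55.3
6,leaf_number_per_plant,11.9,96.0,12.2,96.0,36.7,38.4,0.05,156.6,194.5
7,leaf_area_cm2_per_plant,268.2,4685.1,277.1,4685.1,1256.4,1349.0,0.03,297747.1,406625.8
8,specific_leaf_weight_mg_cm2,0.5,10.0,0.5,10.0,6.0,6.0,0.49,1.0,1.3
9,leaf_dry_weight_g_per_plant,1.7,22.4,1.8,22.4,7.4,8.0,0.02,9.8,12.8
10,leaf_area_index,0.9,15.6,0.9,15.6,4.2,4.5,0.03,3.3,4.5
11,stem_dry_weight_g_per_plant,6.9,104.7,6.9,104.7,32.1,34.2,0.04,169.4,223.7
12,mean_ear_head_weight_g,0.7,12.4,0.7,12.4,4.9,5.0,0.37,4.0,4.9
13,ear_head_weight_g_per_plant,2.9,53.9,2.9,53.9,18.7,19.7,0.07,65.6,87.5
14,seed_yield_g_per_plant,2.0,43.4,2.0,43.4,13.7,14.4,0.11,38.3,51.2
15,total_dry_matter_g_per_plant,11.5,181.1,11.5,181.1,58.6,62.5,0.03,517.1,695.7
16,threshing_pct,41.9,90.9,42.1,89.7,72.9,72.4,0.31,57.4,63.8
17,test_weight_g_1000_seeds,1.0,3.6,1.0,3.6,2.5,2.4,0.79,0.2,0.2
18,harvest_index,0.05,0.45,0.05,0.45,0.2,0.2,0.59,0.0,0.0
19,grain_phytic_acid_mg_100g,488.6,951.0,497.1,951.0,738.0,727.9,0.10,8463.5,8269.2
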