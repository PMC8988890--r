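accession,gpa_level,meal,phytic_acid_mg_100g,fe_mg_100g,native_fe_total_mg,native_fe_per_meal_mg,label,label_fe_mg_per_meal,n_meals
GE2358,low,low_phytate,571,3.6,10.0,3.3,Fe57,1,3
GE1004,high,high_phytate,757,2.8,8.1,2.7,Fe58,1,3
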