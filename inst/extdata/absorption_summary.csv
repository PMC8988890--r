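accession,gpa_level,meal,n,geo_mean_fia,fia_min,fia_max
GE2358,low,low_phytate,10,0.037,0.020,0.074
GE1004,high,high_phytate,10,0.013,0.001,0.055
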