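parameter,unit,mean,sd,min,max
age,y,21.6,3.0,20,30
height,m,1.6,0.1,1.4,1.6
weight,kg,50.5,4.2,41.7,58.4
bmi,kg_m2,20.5,1.5,18.9,23.0
hemoglobin,g_dL,13.7,0.8,12.3,15.0
serum_ferritin,ug_L,25.2,10.1,11.7,40.7
crp,mg_L,1.6,2.1,0.1,6.5
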