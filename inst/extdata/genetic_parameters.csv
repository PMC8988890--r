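season,n_accessions,grand_mean,gv,pv,ev,gcv,pcv,ecv,h2,gam
2015,623,738,8493.1,8738.6,245.5,12.5,12.7,2.1,97.2,25.4
2015,275,721,7855.1,8097.4,242.4,12.3,12.5,2.2,97.0,25.0
2016,275,658,6199.5,6637.7,438.2,12.0,12.4,3.2,93.4,23.9
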