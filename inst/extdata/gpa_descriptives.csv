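season,n_accessions,mean,min,max,sd,sem,cv
2015,623,738,489,951,92,9,12.5
2015,275,721,497,903,90,9,12.4
2016,275,658,478,887,80,12,12.2
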