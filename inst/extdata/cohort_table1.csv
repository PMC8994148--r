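cohort,characteristic,level,n_gbs,n_nongbs
us,total,all,996,78169
us,age,0.5-17,57,13199
us,age,18-49,276,25146
us,age,50-64,326,17147
us,age,>=65,337,22677
us,gender,male,505,23327
eu,total,all,214,12281
eu,age,0.5-17,6,2691
eu,age,18-49,48,3987
eu,age,50-64,74,2548
eu,age,>=65,86,3055
eu,gender,male,125,4949
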