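category,displayGroup,records,taxa,exclusives
pmls,PMLS,16150,504,241
collection,Collections,272,180,77
ecological,Other,840,29,11
literature,Other,12,3,2
crowd,Crowd,2748,316,72
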