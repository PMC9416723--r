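substance_id,metabolite_id,fue,basis,source
deltamethrin,DBCA,0.45,measured_human,five volunteers; 45% molar recovery within 24 h
deltamethrin,3-PBA,0.09,measured_human,lowest reported molar 3-PBA excretion across pyrethroids
cyfluthrin,4-FPBA,0.47,measured_human,single volunteer; 47% molar (25% mass) within two days
cyfluthrin,4-FPBA,0.09,worst_case,conservative screening assumption given single-volunteer evidence
cypermethrin,DCCA,0.36,measured_human,cis/trans combined; single low oral dose volunteers
lambda-cyhalothrin,ClF3CA,0.21,measured_human,seven volunteers over four days; single low oral dose
lambda-cyhalothrin,3-PBA,0.251,measured_human,single-study molar 3-PBA excretion
permethrin,DCCA,0.36,measured_human,trans/cis combined; single low oral dose volunteers
bifenthrin,ClF3CA,0.21,inferred,read-across from lambda-cyhalothrin (same metabolite; similar structure)
tau-fluvalinate,3-PBA,0.09,worst_case,no human toxicokinetic data; conservative scenario
tau-fluvalinate,3-PBA,0.31,inferred,realistic scenario; geomean including cis/trans differences
etofenprox,3-PBA,0.01,worst_case,low reliability; substance flagged non-assessable
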