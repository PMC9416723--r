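id,adi_mg_per_kg_bw_day,mw_g_per_mol,adi_source,assessable
deltamethrin,0.01,505.20,JMPR (adopted within HBM4EU),TRUE
cyfluthrin,0.01,434.29,EFSA (beta-cyfluthrin; conservative for the isomer mixture),TRUE
cypermethrin,0.005,416.30,EFSA,TRUE
lambda-cyhalothrin,0.0025,449.85,EFSA,TRUE
permethrin,0.05,391.29,ECHA,TRUE
bifenthrin,0.015,422.87,EFSA,TRUE
tau-fluvalinate,0.005,502.91,EFSA,TRUE
etofenprox,0.03,376.50,EFSA,FALSE
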