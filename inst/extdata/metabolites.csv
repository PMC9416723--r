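id,mw_g_per_mol,parents,isomer_note
3-PBA,214.22,cypermethrin;deltamethrin;etofenprox;lambda-cyhalothrin;permethrin;tau-fluvalinate,common metabolite; free plus conjugated; also formed from pyrethroids outside this registry
4-FPBA,232.21,cyfluthrin,near-specific; also a flumethrin metabolite
ClF3CA,242.62,bifenthrin;lambda-cyhalothrin,cis isomer; also called CFMP; common with tefluthrin
DBCA,297.97,deltamethrin,cis isomer; specific
DCCA,209.07,cyfluthrin;cypermethrin;permethrin,sum of cis and trans
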