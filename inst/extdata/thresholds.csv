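compound,threshold_mg_per_100g,source
Asp,100,literature placeholder
Glu,30,literature placeholder
Thr,260,literature placeholder
Ser,150,literature placeholder
Gly,130,literature placeholder
Ala,60,literature placeholder
Arg,50,back-derived from reported Arg TAV range
Pro,300,literature placeholder
Val,40,literature placeholder
Met,30,literature placeholder
Leu,190,literature placeholder
Tyr,910,literature placeholder
Phe,90,literature placeholder
Lys,50,literature placeholder
His,20,literature placeholder
Ile,90,literature placeholder
GMP,12.5,literature placeholder
IMP,25,literature placeholder
AMP,50,literature placeholder
Hx,100,literature placeholder
HxR,50,literature placeholder
Na,175,literature placeholder
K,130,literature placeholder
Mg,100,literature placeholder
Ca,190,literature placeholder
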