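drug,weight,unit,source
norepinephrine,1,ug/kg/min,reference drug
epinephrine,1,ug/kg/min,Kotani et al. 2023 updated vasopressor equivalence
phenylephrine,0.1,ug/kg/min,Kotani et al. 2023 updated vasopressor equivalence
dopamine,0.01,ug/kg/min,Kotani et al. 2023 updated vasopressor equivalence
metaraminol,0.125,ug/kg/min,Kotani et al. 2023 updated vasopressor equivalence
vasopressin,2.5,U/min,Kotani et al. 2023 updated vasopressor equivalence
angiotensin_ii,10,ug/kg/min,Kotani et al. 2023 updated vasopressor equivalence
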