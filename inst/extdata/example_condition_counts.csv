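condition,total,lung,colon,rectal,breast,gastric
hypertension,1495,601,222,196,171,305
mild_liver,1046,397,172,154,110,213
renal,821,264,158,163,19,217
diabetes,742,300,106,105,79,152
mi,730,292,119,85,68,166
peptic_ulcer,442,153,77,55,29,128
pvd,379,172,56,60,30,61
copd,358,199,30,52,17,60
cvd,235,110,36,24,13,52
severe_liver,90,28,14,14,8,26
chf,77,33,9,11,0,24
diabetes_comp,49,29,7,4,2,7
connective_tissue,39,22,4,2,5,6
dementia,5,0,0,2,1,2
paralysis,2,0,2,0,0,0
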