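cancer_type,n_patients,n_with_comorbidity
lung,1728,1446
colon,570,480
rectal,582,457
breast,797,385
gastric,989,786
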