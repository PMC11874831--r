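# ICD-10 prefix -> condition dictionary for the cancer-specific comorbidity
# roster (14 NCI Comorbidity Index conditions + hypertension, optional
# connective tissue disease). Prefixes are dot-free, uppercase; a code matches
# a condition if any listed prefix is a leading substring of the normalized
# code. Code lists follow the published Quan et al. (2005) ICD-10 coding of
# the Charlson conditions, relabeled to this roster. Malignancy codes are
# deliberately absent: the index cancer never counts as its own comorbidity.
dialect: quan-icd10-nci15
version: 1
conditions:
  mi:
    label: "Myocardial infarction"
    weight: 1
    icd10: [I21, I22, I252]
  chf:
    label: "Congestive heart failure"
    weight: 1
    icd10: [I099, I110, I130, I132, I255, I420, I425, I426, I427, I428, I429,
            I43, I50, P290]
  pvd:
    label: "Peripheral vascular disease"
    weight: 1
    icd10: [I70, I71, I731, I738, I739, I771, I790, I792, K551, K558, K559,
            Z958, Z959]
  cvd:
    label: "Cerebrovascular disease"
    weight: 1
    icd10: [G45, G46, H340, I60, I61, I62, I63, I64, I65, I66, I67, I68, I69]
  dementia:
    label: "Dementia"
    weight: 1
    icd10: [F00, F01, F02, F03, F051, G30, G311]
  copd:
    label: "Chronic obstructive pulmonary disease"
    weight: 1
    icd10: [I278, I279, J40, J41, J42, J43, J44, J45, J46, J47, J60, J61,
            J62, J63, J64, J65, J66, J67, J684, J701, J703]
  peptic_ulcer:
    label: "Peptic ulcer"
    weight: 1
    icd10: [K25, K26, K27, K28]
  mild_liver:
    label: "Mild liver disease"
    weight: 1
    icd10: [B18, K700, K701, K702, K703, K709, K713, K714, K715, K717, K73,
            K74, K760, K762, K763, K764, K768, K769, Z944]
  diabetes:
    label: "Diabetes"
    weight: 1
    icd10: [E100, E101, E106, E108, E109, E110, E111, E116, E118, E119,
            E120, E121, E126, E128, E129, E130, E131, E136, E138, E139,
            E140, E141, E146, E148, E149]
  diabetes_comp:
    label: "Diabetes with complications"
    weight: 2
    icd10: [E102, E103, E104, E105, E107, E112, E113, E114, E115, E117,
            E122, E123, E124, E125, E127, E132, E133, E134, E135, E137,
            E142, E143, E144, E145, E147]
  paralysis:
    label: "Paralysis (hemiplegia or paraplegia)"
    weight: 2
    icd10: [G041, G114, G801, G802, G81, G82, G830, G831, G832, G833, G834,
            G839]
  renal:
    label: "Renal disease"
    weight: 2
    icd10: [I120, I131, N032, N033, N034, N035, N036, N037, N052, N053,
            N054, N055, N056, N057, N18, N19, N250, Z490, Z491, Z492, Z940,
            Z992]
  severe_liver:
    label: "Moderate/severe liver disease"
    weight: 3
    icd10: [I850, I859, I864, I982, K704, K711, K721, K729, K765, K766,
            K767]
  aids:
    label: "AIDS"
    weight: 6
    icd10: [B20, B21, B22, B24]
  hypertension:
    label: "Hypertension"
    weight: 0
    icd10: [I10, I11, I12, I13, I15]
  connective_tissue:
    label: "Connective tissue disease"
    weight: 1
    optional: true
    icd10: [M05, M06, M315, M32, M33, M34, M351, M353, M360]
# severity hierarchies: when codes for both members are present the more
# severe assignment wins and the milder indicator is forced to zero.
hierarchy:
  - [mild_liver, severe_liver]
  - [diabetes, diabetes_comp]
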