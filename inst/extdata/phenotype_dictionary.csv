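disease,kind,code,term,status,note
asthma,code,C-AST-01,asthma,validated,
asthma,code,C-AST-02,bronchial asthma,validated,
ckd,code,C-CKD-01,chronic kidney disease,validated,
copd,code,C-CPD-01,chronic obstructive pulmonary disease,validated,
dementia,code,C-DEM-01,dementia,validated,
t1dm,code,C-T1D-01,type 1 diabetes mellitus,validated,
t2dm,code,C-T2D-01,type 2 diabetes mellitus,validated,
asthma,term,,asthmatic,validated,
asthma,term,,asthma - mild,validated,
asthma,term,,allergic asthma,validated,
asthma,term,,asthma (exercise induced),validated,
ckd,term,,ckd,validated,
ckd,term,,ckd stage 3,validated,
ckd,term,,chronic renal failure,validated,
ckd,term,,chronic renal impairment,validated,
ckd,term,,crf,validated,
copd,term,,copd,validated,
copd,term,,coad,validated,
copd,term,,chronic obstructive airways disease,validated,
copd,term,,copd - emphysema,validated,
dementia,term,,alzheimer's disease,validated,
dementia,term,,alzheimers dementia,validated,
dementia,term,,vascular dementia,validated,
dementia,term,,dementia - alzheimer type,validated,
t1dm,term,,t1dm,validated,
t1dm,term,,dm1,validated,
t1dm,term,,iddm,validated,
t1dm,term,,type 1 diabetes,validated,
t1dm,term,,diabetes mellitus type 1,validated,
t2dm,term,,t2dm,validated,
t2dm,term,,dmt2,validated,
t2dm,term,,niddm,validated,
t2dm,term,,type 2 diabetes,validated,
t2dm,term,,diabetes mellitus type 2,validated,
asthma,term,,family history of asthma,excluded_ambiguous,
ckd,term,,renal disease,excluded_ambiguous,
copd,term,,smokers cough,excluded_ambiguous,
dementia,term,,?dementia,excluded_ambiguous,
dementia,term,,memory loss,excluded_ambiguous,
t1dm,term,,diabetes,excluded_ambiguous,
t2dm,term,,diabetes,excluded_ambiguous,
asthma,invalid_mapping,C-AST-01,bronchiectasis,,
ckd,invalid_mapping,C-CKD-01,chd - coronary heart disease,,
copd,invalid_mapping,C-CPD-01,chronic cough,,
dementia,invalid_mapping,C-DEM-01,delirium,,
t1dm,invalid_mapping,C-T1D-01,diabetes insipidus,,
t2dm,invalid_mapping,C-T2D-01,gestational diabetes,,
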