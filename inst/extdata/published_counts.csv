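disease,label,coded_n,validated_n,excluded_invalid_n,cohort_n
asthma,Asthma,46853,74038,46,456125
ckd,Chronic kidney disease,8303,10721,1,456125
copd,Chronic obstructive pulmonary disease,7774,9573,9,456125
dementia,Dementia,2153,2525,57,456125
t1dm,Type 1 diabetes,2033,2112,1,456125
t2dm,Type 2 diabetes,23264,23877,3,456125
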