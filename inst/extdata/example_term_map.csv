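raw_term,canonical_term,category
triple vessel disease,Coronary Multivessel Disease,diagnosis
left main disease,Coronary Multivessel Disease,diagnosis
triple coronary disease,Coronary Multivessel Disease,diagnosis
multivessel disease,Coronary Multivessel Disease,diagnosis
hypertension,Hypertension,comorbidity
hypertension stage 2 high-risk group,Hypertension,comorbidity
hypertension stage 3 very high-risk group,Hypertension,comorbidity
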