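record_id,sex,age,admission_year,city,diagnoses,comorbidities
H001,male,58,2014,Nanning,Unstable Angina;triple vessel disease,Hypertension stage 3 very high-risk group;Fatty Liver Disease
H002,female,67,2015,Nanning,Unstable Angina;Braunwald Class II B,hypertension;Dyslipidemia
H003,male,62,2015,Liuzhou,Stable Angina,Hypertension stage 2 high-risk group;Metabolic Diseases
H004,male,55,2016,Nanning,Myocardial Infarction;KILLIP Class I,hypertension;Diabetes and Its Complications
H005,female,71,2016,Guilin,Unstable Angina,Dyslipidemia;Cardiac Arrhythmias
H006,male,64,2017,Nanning,multivessel disease;Unstable Angina,hypertension;Renal Cysts
H007,female,69,2018,Nanning,Coronary Atherosclerosis,hypertension;Diabetes and Its Complications
H008,male,59,2018,Nanning,Unstable Angina;Braunwald Class III B,Metabolic Diseases;Fatty Liver Disease
H009,male,48,2019,Baise,Myocardial Infarction,Tobacco dependence;hypertension
H010,female,74,2019,Nanning,Stable Angina;CCS Angina class II,Hypertension stage 3 very high-risk group;Skeletal Diseases
H011,male,66,2020,Nanning,Unstable Angina,hypertension;Dyslipidemia;Metabolic Diseases
H012,female,63,2020,Liuzhou,Braunwald Class II B;Unstable Angina,Cardiac Arrhythmias;hypertension
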