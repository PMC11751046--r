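stratum,drug1,drug2,ae,n111,omega025,lift,conviction,confidence
overall,Amlodipine,Atorvastatin,Jaundice,12,3.08,1116.69,1.75,0.43
overall,Aspirin,Ticagrelor,Epistaxis,11,1.04,89.14,1.09,0.09
overall,Aspirin,Clopidogrel,Petechiae,4,0.14,63.81,1.05,0.05
overall,Aspirin,Clopidogrel,Haematochezia,13,0.04,55.83,1.06,0.06
overall,Aspirin,Ticagrelor,Haemorrhage,10,0.04,45.31,1.07,0.07
overall,Aspirin,Clopidogrel,Haemoptysis,6,0.36,44.01,1.033,0.03
overall,Aspirin,Ticagrelor,Gingival bleeding,8,0.02,36.78,1.08,0.08
overall,Nifedipine,Aspirin,Skin reaction,6,0.18,11.60,1.11,0.11
overall,Vitamin B6,Vitamin C,Chills,6,1.02,7.49,1.13,0.13
male,Amlodipine,Atorvastatin,Jaundice,8,2.55,908.32,2.00,0.5
male,Aspirin,Ticagrelor,Cerebral haemorrhage,3,0.74,205.56,1.04,0.04
male,Aspirin,Ticagrelor,Epistaxis,8,0.455,73.41,1.11,0.10
male,Aspirin,Ticagrelor,Petechial rash,3,0.05,67.45,1.03,0.03
male,Aspirin,Clopidogrel,Melaena,7,0.01,55.97,1.05,0.05
male,Aspirin,Ticagrelor,Gastrointestinal haemorrhage,12,0.15,44.54,1.14,0.13
male,Aspirin,Ticagrelor,Haemoptysis,5,0.39,39.97,1.05,0.005
female,Amlodipine,Atorvastatin,Jaundice,4,1.46,1391.53,1.50,0.33
female,Aspirin,Ticagrelor,Upper gastrointestinal haemorrhage,5,0.08,121.71,1.11,0.10
female,Aspirin,Ticagrelor,Haemorrhage,6,0.66,102.24,1.14,0.12
female,Aspirin,Clopidogrel,Upper gastrointestinal haemorrhage,7,0.18,82.67,1.07,0.07
female,Vitamin B6,Vitamin C,Chills,5,0.89,7.15,1.12,0.12
age_ge60,Amlodipine,Atorvastatin,Jaundice,5,1.80,1061.53,1.56,0.36
age_ge60,Aspirin,Ticagrelor,Epistaxis,8,1.09,95.63,1.10,0.09
age_ge60,Vitamin B6,Vitamin C,Chills,5,0.27,7.99,1.17,0.17
age_lt60,Amlodipine,Atorvastatin,Jaundice,7,2.35,1024.08,2.00,0.50
age_lt60,Aspirin,Clopidogrel,Haematochezia,4,0.80,121.37,1.10,0.09
age_lt60,Irbesartan,Felodipine,Palpitations,3,0.41,14.65,3.80,0.75
age_lt60,compound Danshen tablets,Nifedipine,Erythema,5,0.23,8.17,1.077,0.08
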