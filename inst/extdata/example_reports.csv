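id,year,age,sex,unit,diseases,drugs,aes,causality
R0001,2021,48,M,Pharmaceutical Enterprise,Hypertension;Hyperlipemia,Amlodipine;Atorvastatin,Jaundice,probable
R0002,2021,55,F,Hospital,Hypertension,Amlodipine,Rash,possible
R0003,2020,59,M,Hospital,Acute Myocardial Infarction,Aspirin;Ticagrelor,Lower Gastrointestinal Bleeding,certain
R0004,2022,77,F,Hospital,Cerebral Infarction;Coronary Heart Disease,Xuesaitong;Sodium Chloride Injection,Local Redness,possible
R0005,2018,87,F,Pharmaceutical Enterprise,Arrhythmia;Lung Infection,Potassium Chloride Injection;Vitamin C Injection,Shiver;Tachypnea,possible
R0006,2013,66,M,Hospital,Hypertension,Nifedipine,Flushing,probable
R0007,2019,71,F,Hospital,Coronary Heart Disease,aspirin ;clopidogrel,gastrointestinal haemorrhage,possible
R0008,2020,63,M,Hospital,Hypertension,Amlodipine;Amlodipine,Headache,unlikely
R0009,2017,,unknown,Hospital,Cerebral Infarction,Xuesaitong,Dizziness,possible
R0010,2016,52,F,Hospital,Hypertension,Nifedipine,,possible
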