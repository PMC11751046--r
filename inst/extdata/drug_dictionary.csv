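raw,standard
aspirin,Aspirin
acetylsalicylic acid,Aspirin
clopidogrel,Clopidogrel
amlodipine,Amlodipine
atorvastatin,Atorvastatin
nifedipine,Nifedipine
ticagrelor,Ticagrelor
xuesaitong,Xuesaitong
vitamin c injection,Vitamin C
potassium chloride injection,Potassium Chloride
sodium chloride injection,Sodium Chloride
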