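raw,standard,category
jaundice,Jaundice,Hepatobiliary disorders
rash,Rash,Skin and subcutaneous tissue disorders
nose bleed,Epistaxis,Respiratory disorders
lower gastrointestinal bleeding,Lower gastrointestinal haemorrhage,Gastrointestinal disorders
gastrointestinal haemorrhage,Gastrointestinal haemorrhage,Gastrointestinal disorders
local redness,Erythema,Skin and subcutaneous tissue disorders
shiver,Chills,General disorders
tachypnea,Tachypnoea,Respiratory disorders
flushing,Flushing,General disorders
headache,Headache,Nervous system disorders
dizziness,Dizziness,Nervous system disorders
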