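feature,sex,age_group,pearson_r,p_value
Bcells,female,6,0.45,0.001
Bcells,female,12,0.40,0.002
Bcells,male,6,0.25,0.02
LYMPH,female,6,0.42,0.001
LYMPH,female,12,0.38,0.003
LYMPH,male,6,0.22,0.03
RBC,male,6,0.45,0.001
RBC,male,12,0.42,0.002
RBC,female,6,0.25,0.02
HGB,male,6,0.43,0.001
HGB,male,12,0.40,0.002
HGB,female,6,0.24,0.02
HCT,male,6,0.41,0.001
HCT,male,12,0.39,0.002
HCT,female,6,0.23,0.03
Mg,female,12,0.42,0.002
Mg,male,12,0.40,0.002
NEUT,female,6,-0.40,0.001
NEUT,female,12,-0.35,0.004
NEUT,male,6,-0.38,0.002
NEUT,male,12,-0.36,0.003
Fe,female,12,-0.40,0.002
Fe,male,12,-0.38,0.002
CHr,female,12,-0.30,0.01
CHr,male,12,-0.28,0.01
T4,male,6,-0.40,0.002
T4,female,12,0.40,0.002
T4,female,18,0.38,0.003
BMI,female,6,-0.40,0.002
BMI,male,6,-0.42,0.001
HR,female,6,-0.38,0.002
HR,male,6,-0.39,0.002
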