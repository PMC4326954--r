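feature,sex,slope_m,p_value
Bcells,female,-0.020,0.0001
Bcells,male,-0.018,0.001
LYMPH,female,-0.019,0.0001
LYMPH,male,-0.017,0.001
RBC,female,-0.021,0.0001
RBC,male,-0.022,0.0001
HGB,female,-0.020,0.0002
HGB,male,-0.021,0.0001
HCT,female,-0.019,0.0003
HCT,male,-0.020,0.0002
Mg,female,-0.030,0.0001
Mg,male,-0.012,0.04
NEUT,female,0.025,0.0001
NEUT,male,0.027,0.0001
Fe,female,-0.020,0.001
Fe,male,-0.019,0.001
CHr,female,-0.015,0.01
CHr,male,-0.014,0.01
T4,female,-0.015,0.01
T4,male,-0.016,0.008
BMI,female,-0.020,0.001
BMI,male,-0.021,0.001
HR,female,-0.018,0.002
HR,male,-0.019,0.002
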