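feature_name,early_effect,late_effect,label,source
Bcells,beneficial,beneficial,anti-immunosenescent,literature
LYMPH,beneficial,beneficial,anti-immunosenescent,literature
RBC,beneficial,beneficial,anti-anaemic,literature
HGB,beneficial,beneficial,anti-anaemic,literature
HCT,beneficial,beneficial,anti-anaemic,literature
Mg,beneficial,beneficial,anti-inflammatory,literature
NEUT,deleterious,deleterious,pro-inflammatory,literature
Fe,deleterious,beneficial,damaging by oxidative stress early; anti-anaemic late,literature
CHr,deleterious,beneficial,damaging by oxidative stress early; anti-anaemic late,literature
T4,deleterious,beneficial,pro-anabolic early; pro-robustness late,literature
BMI,deleterious,beneficial,pro-anabolic early; pro-robustness late,literature
HR,deleterious,beneficial,pro-anabolic early; pro-robustness late,literature
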