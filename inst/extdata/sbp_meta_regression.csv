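term,estimate,unit,source
slope_per_g,0.64,mmHg SBP change per g/day salt change,externally sourced default derived from the 103-trial sodium-BP meta-regression (3.74 mmHg per 100 mmol/day sodium); exact appendix coefficients not printed in main text
age_per_decade,0.11,additional mmHg per g/day per decade of age above 50,externally sourced default from the same meta-regression; flagged approximate
hypertension_extra,0.42,additional mmHg per g/day when baseline SBP >= 140 mmHg,externally sourced default from the same meta-regression; flagged approximate
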