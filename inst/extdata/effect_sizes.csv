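disease,factor,unit,rr_per_unit,ci_low,ci_high,lag_mean,source
chd,sbp,per mmHg above 115,1.030,1.025,1.035,5,externally sourced default: prospective BP meta-analyses (e.g. Lewington 2002); not printed in main text
stroke,sbp,per mmHg above 115,1.040,1.033,1.047,5,externally sourced default: prospective BP meta-analyses (e.g. Lewington 2002); not printed in main text
gca,salt,per g/day above ideal,1.080,1.030,1.130,8,externally sourced default: salt-gastric-cancer dose-response meta-analyses (e.g. D'Elia 2012); not printed in main text
chd,bmi,per kg/m2 above 21,1.050,1.030,1.070,5,externally sourced default: BMI-CHD meta-analyses; not printed in main text
stroke,bmi,per kg/m2 above 21,1.040,1.020,1.060,5,externally sourced default: BMI-stroke meta-analyses; not printed in main text
gca,bmi,per kg/m2 above 21,1.020,1.000,1.040,8,externally sourced default; not printed in main text
chd,tchol,per mmol/L above 3.8,1.200,1.100,1.310,5,externally sourced default: cholesterol-CHD meta-analyses; not printed in main text
chd,diabetes,presence,2.000,1.700,2.350,5,externally sourced default; not printed in main text
stroke,diabetes,presence,1.700,1.400,2.060,5,externally sourced default; not printed in main text
chd,smoking,current smoker,2.000,1.800,2.220,5,externally sourced default; not printed in main text
stroke,smoking,current smoker,1.800,1.600,2.030,5,externally sourced default; not printed in main text
gca,smoking,current smoker,1.600,1.400,1.830,5,externally sourced default; lag follows the CVD lag per the smoking-on-GCa assumption
chd,ets,presence,1.250,1.100,1.420,5,externally sourced default; not printed in main text
chd,fv_deficit,per portion/day below 5,1.040,1.010,1.070,5,externally sourced default: fruit&veg-CHD meta-analyses; not printed in main text
gca,fv_deficit2,per portion/day below 2,1.150,1.050,1.260,8,externally sourced default: low fruit&veg and GCa; not printed in main text
chd,pa_deficit,per active day/week below 5,1.030,1.000,1.060,5,externally sourced default; not printed in main text
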