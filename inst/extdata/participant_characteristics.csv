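variable,young_mean,young_sd,middle_mean,middle_sd,n_per_group
age_years,25,4,60,7,12
height_cm,170.3,8.7,167.8,9.3,12
weight_kg,67.2,11.3,71.7,18.5,12
bmi_kg_m2,23.0,1.9,25.2,4.5,12
fat_mass_pct,19.5,6.4,29.7,8.9,12
hrmax_bpm,184,4,150,15,12
vo2peak_ml_kg_min,40.9,8.6,27.9,6.6,12
vo2peak_l_min,2.06,0.80,2.78,0.85,12
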