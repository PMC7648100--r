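exposure	outcome	or	ci_low	ci_high
smoking_status	CD	1.13	1.02	1.25
smoking_status	UC	0.99	0.90	1.10
cigarettes_per_day	CD	1.17	0.94	1.44
cigarettes_per_day	UC	0.90	0.73	1.10
body_mass_index	CD	1.11	1.02	1.20
body_mass_index	UC	0.85	0.78	0.92
waist_hip_ratio	CD	1.22	1.09	1.37
waist_hip_ratio	UC	0.90	0.81	1.01
body_fat_percentage	CD	1.50	1.32	1.71
body_fat_percentage	UC	1.11	0.98	1.25
physical_activity	IBD	0.51	0.27	0.98
vitamin_d	IBD	0.96	0.87	1.06
vitamin_b9	IBD	0.83	0.67	1.03
vitamin_b12	CD	1.10	1.00	1.21
vitamin_b12	UC	1.06	0.97	1.15
omega3_fatty_acids	IBD	0.78	0.68	0.88
omega3_fatty_acids	CD	0.67	0.56	0.79
omega3_fatty_acids	UC	0.88	0.75	1.03
omega6_fatty_acids	IBD	0.96	0.88	1.05
monounsaturated_fa	IBD	0.94	0.82	1.08
total_fatty_acids	IBD	0.94	0.85	1.04
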