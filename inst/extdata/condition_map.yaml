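# Example mapping from EMR source condition strings to the penrisk
# controlled vocabulary (see condition_vocabulary()).
"atrial_fibrillation": other_cvd
"Atrial Fibrillation": other_cvd
"IHD - stable angina": stable_angina
"IHD - unstable angina": unstable_angina
"MI": myocardial_infarction
"Myocardial infarction": myocardial_infarction
"PTCA": angioplasty
"CHF": congestive_heart_failure
"PVD": peripheral_vascular_disease
"Stroke": cv_or_cerebrovascular_complication
"TIA": cv_or_cerebrovascular_complication
"HTN": hypertension
"Hypertension": hypertension
"Diabetes mellitus": diabetes
"DM": diabetes
"COPD": copd
"Asthma": asthma
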