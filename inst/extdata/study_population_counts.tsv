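metric	value
n_subjects	335
n_female	213
n_male	122
mean_age_female	43.9
mean_age_male	46.1
n_reference_mirnas	3524
n_detected_mirnas	3277
n_detected_half_samples	449
n_detected_for_de	3041
n_demirnas_any_variable	151
n_demirnas_multi_variable	52
n_demirnas_bmi	92
n_demirnas_smoking	84
n_never_smokers	181
n_repeat_subjects	6
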