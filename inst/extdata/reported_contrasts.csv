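contrast,delta_atu,total_atu
max_family_difference_treatment_A,28,527
max_fert_date_difference_treatment_B,33,521
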