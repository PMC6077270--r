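channel,compartment,control_mean,treated_mean,n_control,n_treated,percent_change
edu,proliferating,515.48373458787,297.099983642577,2,2,42.3648189636655
protein,proliferating,443.178273484929,223.381057220034,2,2,49.5956659915932
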