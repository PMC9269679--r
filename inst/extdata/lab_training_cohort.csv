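condition,step_length_left_m,step_length_right_m,step_length_left_sd_m,step_length_right_sd_m,gait_speed_mps,n_steps
barefoot,0.37,0.389,0.052,0.038,0.876,1
barefoot,0.465,0.473,0.013,0.03,1.019,1
barefoot,0.282,0.444,0.037,0.013,0.389,2
barefoot,0.457,0.417,0.012,0.02,0.797,1
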