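condition,step_length_left_m,step_length_right_m,step_length_left_sd_m,step_length_right_sd_m,gait_speed_mps,n_steps_left,n_steps_right
barefoot,0.149,0.24,0.06,0.056,0.134,7,7
barefoot,0.467,0.501,0.046,0.045,1.133,29,30
shoes_orthotics,0.439,0.485,0.053,0.053,0.979,43,41
barefoot,0.254,0.032,0.014,0.01,0.184,27,21
shoes_orthotics,0.278,0.058,0.017,0.025,0.228,11,12
barefoot,0.222,0.25,0.023,0.011,0.287,10,11
shoes_orthotics,0.284,0.362,0.024,0.022,0.449,8,8
barefoot,0.475,0.14,0.024,0.022,0.237,24,22
shoes_orthotics,0.478,0.186,0.02,0.042,0.273,29,28
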