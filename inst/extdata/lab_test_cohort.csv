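condition,step_length_left_m,step_length_right_m,step_length_left_sd_m,step_length_right_sd_m,gait_speed_mps,n_steps_left,n_steps_right
barefoot,0.56,0.609,0.047,0.043,1.292,16,16
barefoot,0.318,0.345,0.027,0.021,0.837,24,23
shoes_orthotics,0.341,0.36,0.052,0.041,0.87,7,7
barefoot,0.471,0.496,0.032,0.044,1.053,23,21
barefoot,0.451,0.452,0.036,0.037,1.028,20,20
barefoot,0.298,0.315,0.037,0.045,0.823,23,22
barefoot,0.306,0.457,0.022,0.016,0.399,5,4
barefoot,0.507,0.501,0.049,0.013,1.256,19,19
barefoot,0.446,0.423,0.022,0.016,0.814,25,22
barefoot,0.538,0.502,0.026,0.063,1.153,24,23
barefoot,0.389,0.439,0.043,0.025,0.771,21,20
barefoot,0.573,0.604,0.023,0.017,0.998,20,18
barefoot,0.511,0.521,0.05,0.03,1.092,23,21
barefoot,0.336,0.341,0.036,0.024,0.845,32,30
barefoot,NA,0.446,NA,0.015,0.699,9,10
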