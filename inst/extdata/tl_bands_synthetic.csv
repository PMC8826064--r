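center_hz,a_db,b_near,b_far,crossover_m
62.5,1.0,15.8,23.0,450
125,1.5,16.0,23.0,450
250,2.0,16.3,23.5,400
500,2.5,16.5,23.5,400
1000,3.5,17.0,24.0,350
2000,5.0,17.5,24.0,350
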