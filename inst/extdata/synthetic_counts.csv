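study,events_trt,total_trt,events_ctl,total_ctl
trial_1,5,40,4,42
trial_2,0,55,11,50
trial_3,17,120,17,115
trial_4,4,34,12,36
trial_5,12,80,9,85
trial_6,7,60,10,58
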