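study,yi,vi
trial_1,-0.003,0.706
trial_2,1.335,0.159
trial_3,-0.386,0.135
trial_4,2.885,0.622
trial_5,0.472,0.735
trial_6,0.133,0.652
trial_7,0.729,0.265
trial_8,-0.398,0.624
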