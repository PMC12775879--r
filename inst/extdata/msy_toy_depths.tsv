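sample_id	mean_depth_autosomes	mean_depth_X	mean_depth_Y
M1	30.1	15.2	14.0
M2	29.5	14.8	13.6
M3	31.2	15.9	14.9
M4	28.7	14.1	13.2
M5	30.8	15.5	14.4
F1	30.3	30.1	0.21
F2	29.9	29.6	0.18
F3	31.5	31.0	0.25
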