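# example pipeline configuration
frame_interval = 2.67

[preprocess]
threshold_sd = 4
min_dwell_frames = 3

[histogram]
bandwidth_t = 5
bandwidth_e = 0.05

[hmm]
n_starts = 5
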