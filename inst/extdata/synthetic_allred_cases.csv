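case_id,fraction,intensity
S001,0,0
S002,0.004,1
S003,0.02,1
S004,0.08,2
S005,0.25,2
S006,0.4,1
S007,0.5,3
S008,0.7,2
S009,0.85,3
S010,1,3
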