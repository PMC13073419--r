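participant,emg_acti,emg_video,acti_video
1,0.25,0.58,0.34
2,0.08,0.28,0.21
3,0.40,0.41,0.34
4,0.34,0.27,0.60
5,0.27,0.32,0.48
6,0.39,0.59,0.54
7,0.24,0.58,0.39
8,0.19,0.39,0.43
9,0.27,0.63,0.36
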