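region,count
emg_only,929
acti_only,883
video_only,68
emg_acti,174
emg_video,187
acti_video,143
all_three,413
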