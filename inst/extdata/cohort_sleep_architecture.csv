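participant,total_sleep_min,rem_min,rem_periods
1,273,51.55,3
2,326,93.5,2
3,312,42.55,3
4,487.5,83.55,3
5,413,97.85,2
6,410.5,45,3
7,404.5,83.5,4
8,521.5,111.55,4
9,392,38,1
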