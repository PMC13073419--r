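participant,ratio_emg,ratio_acti,ratio_video,rate_emg,rate_acti,rate_video
1,5.04,19.79,5.53,32.59,72.16,32.59
2,2.14,15.56,4.71,22.46,106.52,46.20
3,8.34,12.22,4.82,57.81,88.84,29.61
4,8.26,3.41,1.86,60.32,26.57,13.64
5,26.37,12.47,7.31,133.67,74.20,42.31
6,21.56,21.00,15.89,114.67,101.33,78.67
7,1.14,4.43,1.74,8.62,17.25,9.34
8,27.43,12.82,10.04,128.01,52.71,65.08
9,8.03,21.58,7.24,42.63,90.00,31.58
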